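#' Parse an OBO flat file into an ontology DAG
#'
#' Reads the stanza-based OBO 1.2/1.4 flat-file dialect and builds a directed
#' acyclic graph over the non-obsolete `[Term]` stanzas, using only `is_a`
#' edges. Other relationship types (`relationship: part_of` and friends),
#' intersections and synonyms are ignored. `alt_id` entries are recorded so
#' that annotations carrying a superseded accession resolve to the primary
#' term.
#'
#' No installed R package in this stack parses OBO, so the (small) stanza
#' grammar is handled here directly.
#'
#' @param path Path to an OBO flat file.
#' @return An object of class `ontology_dag`: a list with elements
#'   \describe{
#'     \item{ids}{character vector of primary term ids, in file order}
#'     \item{names}{named character vector of term labels}
#'     \item{parents}{named list, term id -> character vector of is-a parents}
#'     \item{children}{named list, the reverse adjacency}
#'     \item{ancestors}{named list, term id -> reflexive transitive is-a
#'       closure (the term itself is always included)}
#'     \item{roots}{term ids with no parents}
#'     \item{alt_ids}{named character vector mapping alternate -> primary id}
#'     \item{obsolete}{character vector of obsolete term ids (excluded from
#'       the graph and from annotation)}
#'   }
#' @details Load fails with an informative error if an `is_a` target is not
#'   defined in the file or if the is-a relation contains a cycle (the error
#'   names one term on the cycle).
#' @examples
#' obo <- system.file("extdata", "toy_cardiac.obo", package = "phenoclust")
#' dag <- parse_obo(obo)
#' dag$roots
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) {
    stop("OBO file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)     # strip trailing OBO comments
  lines <- trimws(lines)

  stanza_starts <- which(lines == "[Term]")
  other_stanzas <- grep("^\\[(?!Term\\])", lines, perl = TRUE)
  bounds <- sort(c(stanza_starts, other_stanzas, length(lines) + 1L))

  ids <- character(0)
  nm <- character(0)
  parents <- list()
  obsolete <- character(0)
  alt_map <- character(0)

  for (s in stanza_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[s:end]
    grab <- function(key) {
      hits <- grep(paste0("^", key, ":"), body, value = TRUE)
      trimws(sub(paste0("^", key, ":"), "", hits))
    }
    id <- grab("id")
    if (length(id) != 1L || !nzchar(id)) {
      stop("OBO [Term] stanza at line ", s, " lacks a single id")
    }
    is_obs <- any(tolower(grab("is_obsolete")) == "true")
    if (is_obs) {
      obsolete <- c(obsolete, id)
      next
    }
    if (id %in% ids) stop("duplicate term id in OBO file: ", id)
    ids <- c(ids, id)
    label <- grab("name")
    nm[id] <- if (length(label)) label[1] else id
    isa <- grab("is_a")
    parents[[id]] <- if (length(isa)) unique(isa) else character(0)
    for (alt in grab("alt_id")) alt_map[alt] <- id
  }

  if (!length(ids)) stop("no non-obsolete [Term] stanzas in ", path)

  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown)) {
    bad <- vapply(ids, function(i) any(parents[[i]] %in% unknown), logical(1))
    stop("is_a target(s) not defined in file: ",
         paste(unknown, collapse = ", "),
         " (referenced by ", paste(ids[bad], collapse = ", "), ")")
  }

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (i in ids) children[[i]] <- character(0)
  for (i in ids) for (p in parents[[i]]) children[[p]] <- c(children[[p]], i)

  anc <- .ancestor_closure(ids, parents)

  dag <- structure(
    list(ids = ids, names = nm, parents = parents, children = children,
         ancestors = anc,
         roots = ids[vapply(parents[ids], length, 1L) == 0L],
         alt_ids = alt_map, obsolete = obsolete),
    class = "ontology_dag")
  dag
}

# Reflexive transitive closure by topological order; detects cycles.
.ancestor_closure <- function(ids, parents) {
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  indeg <- vapply(parents[ids], length, 1L)   # edges point child -> parent
  anc <- stats::setNames(vector("list", n), ids)
  # process parents before children: topological order on parent -> child
  nkids <- integer(n)
  kids <- stats::setNames(vector("list", n), ids)
  for (i in ids) kids[[i]] <- character(0)
  for (i in ids) for (p in parents[[i]]) kids[[p]] <- c(kids[[p]], i)
  queue <- ids[indeg == 0L]
  remaining <- indeg
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    anc[[t]] <- sort(unique(c(t, unlist(anc[parents[[t]]], use.names = FALSE))))
    for (ch in kids[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < n) {
    on_cycle <- ids[remaining[ids] > 0L]
    stop("cycle detected in is_a relation involving term(s): ",
         paste(utils::head(on_cycle, 5L), collapse = ", "))
  }
  anc
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$ids), "terms,",
      sum(lengths(x$parents)), "is-a edges,",
      length(x$roots), "root(s)\n")
  if (length(x$obsolete)) {
    cat("  obsolete (excluded):", length(x$obsolete), "\n")
  }
  invisible(x)
}

.resolve_term <- function(dag, t) {
  if (t %in% dag$ids) return(t)
  if (t %in% names(dag$alt_ids)) return(unname(dag$alt_ids[[t]]))
  stop("unknown term id: ", t)
}

#' Ancestors of a term
#'
#' Reflexive transitive closure over is-a edges: `t` is always a member of
#' its own ancestor set, which makes the Resnik self-similarity of a term
#' equal to its own information content.
#'
#' @param dag An `ontology_dag` from [parse_obo()].
#' @param t A term id (primary or alt id).
#' @return Character vector of term ids (sorted), including `t` itself.
#' @export
ancestors <- function(dag, t) {
  stopifnot(inherits(dag, "ontology_dag"))
  dag$ancestors[[.resolve_term(dag, t)]]
}

#' Common ancestors of two terms
#'
#' Intersection of the reflexive ancestor closures of `s` and `t`. With a
#' single-rooted ontology the result always contains the root; on
#' multi-rooted toy ontologies it may be empty, in which case the term
#' similarity is defined as zero.
#'
#' @inheritParams ancestors
#' @param s,t Term ids.
#' @return Character vector of shared ancestor ids (possibly empty).
#' @export
common_ancestors <- function(dag, s, t) {
  intersect(ancestors(dag, s), ancestors(dag, t))
}

#' Remap a term onto a supported vocabulary
#'
#' When an annotated term is not part of the supported similarity vocabulary,
#' its nearest supported superclass is substituted (minimum number of is-a
#' edges walked upward). Ties at equal edge distance break deterministically
#' to the lexicographically smallest term id.
#'
#' @inheritParams ancestors
#' @param supported Character vector of supported term ids.
#' @return A single term id in `supported`.
#' @export
remap_to_supported <- function(dag, t, supported) {
  stopifnot(inherits(dag, "ontology_dag"), length(supported) > 0L)
  t <- .resolve_term(dag, t)
  # breadth-first walk upward; depth 0 is t itself
  frontier <- t
  visited <- character(0)
  repeat {
    hit <- sort(intersect(frontier, supported))
    if (length(hit)) return(hit[[1L]])
    visited <- c(visited, frontier)
    frontier <- setdiff(
      unique(unlist(dag$parents[frontier], use.names = FALSE)), visited)
    if (!length(frontier)) {
      stop("term ", t, " has no supported ancestor")
    }
  }
}
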