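#' Resnik similarity of two ontology terms
#'
#' The similarity of terms `s` and `t` is the information content of their
#' most informative common ancestor: `sim(s, t) = max IC(v)` over all shared
#' ancestors `v`. Because the ancestor closure is reflexive, a term's
#' self-similarity equals its own IC. Common ancestors without an IC entry
#' (never observed in the cohort) contribute nothing; if no common ancestor
#' carries information — including the empty-intersection case on
#' multi-rooted ontologies — the similarity is 0.
#'
#' @param s,t Term ids.
#' @param ic An `ic_table` from [information_content()].
#' @param dag The `ontology_dag`.
#' @return A scalar similarity, `>= 0`.
#' @export
term_similarity <- function(s, t, ic, dag) {
  ca <- common_ancestors(dag, s, t)
  icv <- ic_vector(ic)
  vals <- icv[intersect(ca, names(icv))]
  if (!length(vals)) 0 else max(vals)
}

#' Best-match-average similarity of two term sets
#'
#' Symmetric set-level similarity between two patients' phenotype profiles
#' `Da` and `Db`: every term in one set is matched to its most similar term
#' in the other set, the best-match scores are averaged within each
#' direction, and the two directional averages are averaged,
#' \deqn{sim(D_a, D_b) = \frac{1}{2|D_a|}\sum_{s \in D_a}\max_{t \in D_b} sim(s,t)
#'   + \frac{1}{2|D_b|}\sum_{t \in D_b}\max_{s \in D_a} sim(s,t).}
#' A profile compared with itself scores the mean IC of its terms (each term
#' best-matches itself under propagated-closure IC).
#'
#' @param Da,Db Character vectors of term ids; both non-empty.
#' @inheritParams term_similarity
#' @return A scalar similarity, `>= 0`.
#' @export
set_similarity <- function(Da, Db, ic, dag) {
  if (!length(Da) || !length(Db)) stop("term sets must be non-empty")
  Da <- sort(unique(Da)); Db <- sort(unique(Db))
  ts <- .term_sim_matrix(union(Da, Db), ic, dag)
  sub <- ts[Da, Db, drop = FALSE]
  mean(apply(sub, 1L, max)) / 2 + mean(apply(sub, 2L, max)) / 2
}

# Dense term-by-term Resnik similarity over `terms` (sorted), using the
# precomputed ancestor closure. Accumulation order is fixed by the sort so
# results are reproducible run to run.
.term_sim_matrix <- function(terms, ic, dag) {
  terms <- sort(unique(terms))
  icv <- ic_vector(ic)
  m <- length(terms)
  out <- matrix(0, m, m, dimnames = list(terms, terms))
  anc <- lapply(terms, function(t) {
    a <- ancestors(dag, t)
    a[a %in% names(icv)]
  })
  for (i in seq_len(m)) {
    ai <- anc[[i]]
    for (j in i:m) {
      ca <- intersect(ai, anc[[j]])
      if (length(ca)) {
        v <- max(icv[ca])
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  out
}

#' Pairwise patient similarity matrix
#'
#' Computes the full symmetric matrix of best-match-average similarities
#' over all patient pairs (diagonal included). Internally the best match of
#' every vocabulary term against every patient is tabulated once, after
#' which the double sum collapses to a matrix product, so cohorts of several
#' hundred patients are handled in well under a second; the result is
#' identical to evaluating the set-similarity formula pair by pair.
#'
#' @param cohort A `phenotype_cohort`.
#' @inheritParams term_similarity
#' @return An object of class `patient_similarity`: list with `patient_ids`,
#'   `sim` (n x n named matrix) and `max_sim` (the matrix maximum).
#' @export
similarity_matrix <- function(cohort, ic, dag) {
  stopifnot(inherits(cohort, "phenotype_cohort"))
  sets <- cohort$term_sets
  pid <- names(sets)
  n <- length(sets)
  vocab <- sort(unique(unlist(sets, use.names = FALSE)))
  ts <- .term_sim_matrix(vocab, ic, dag)

  # best[s, j] = max over t in D_j of sim(s, t)
  best <- vapply(sets, function(d) {
    sub <- ts[, d, drop = FALSE]
    apply(sub, 1L, max)
  }, numeric(length(vocab)))

  # membership matrix P (n x m): row sums are the profile sizes |D_j|
  P <- matrix(0, n, length(vocab), dimnames = list(pid, vocab))
  for (j in seq_len(n)) P[j, sets[[j]]] <- 1
  sizes <- rowSums(P)

  directional <- (P %*% best) / sizes      # [a, b] = mean best match Da -> Db
  sim <- (directional + t(directional)) / 2
  dimnames(sim) <- list(pid, pid)

  structure(list(patient_ids = pid, sim = sim, max_sim = max(sim)),
            class = "patient_similarity")
}

#' @export
print.patient_similarity <- function(x, ...) {
  cat("patient_similarity:", length(x$patient_ids), "patients, max",
      format(x$max_sim, digits = 4), "\n")
  invisible(x)
}

#' Distance transform of a similarity matrix
#'
#' Converts similarities to dissimilarities as `max(sim_mat) - sim_mat`,
#' where the maximum is taken over the full matrix including the diagonal.
#' Self-similarity varies from patient to patient, so the raw transform
#' leaves a positive diagonal; the diagonal is therefore forced to exactly 0
#' (the default) so that the result is a valid dissimilarity for
#' agglomerative clustering.
#'
#' @param simmat A `patient_similarity`.
#' @param zero_diagonal Force the diagonal to 0 (default `TRUE`).
#' @return An object of class `patient_distance`: list with `patient_ids`,
#'   `dist` (n x n matrix) and `max_sim` (the similarity maximum used).
#' @export
to_distance <- function(simmat, zero_diagonal = TRUE) {
  stopifnot(inherits(simmat, "patient_similarity"))
  d <- simmat$max_sim - simmat$sim
  if (zero_diagonal) diag(d) <- 0
  structure(list(patient_ids = simmat$patient_ids, dist = d,
                 max_sim = simmat$max_sim),
            class = "patient_distance")
}

#' Write a patient matrix (similarity or distance) to TSV
#'
#' Emits the matrix with a patient-id header row and column, plus a JSON
#' sidecar (`<path>.json`) recording the IC closure mode, log base and the
#' similarity maximum so a matrix can be reinterpreted without rerunning.
#'
#' @param x A `patient_similarity` or `patient_distance`.
#' @param path Output TSV path.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_patient_matrix <- function(x, path, meta = list()) {
  m <- if (inherits(x, "patient_similarity")) x$sim else x$dist
  tab <- data.frame(patient_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(kind = class(x)[1], max_sim = x$max_sim,
                 n = length(x$patient_ids)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a patient matrix written by [write_patient_matrix()]
#' @param path TSV path.
#' @return The named numeric matrix.
#' @export
read_patient_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$patient_id
  m
}
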