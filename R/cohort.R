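#' Load a patient phenotype cohort from TSV
#'
#' Reads the tab-separated cohort format: one row per patient with columns
#' `patient_id`, `hpo_terms` (pipe-separated ontology term ids),
#' `age_at_surgery` (years), `sex` (`female`/`male`), `bmi`,
#' `family_history` (0/1, optional), `surgery`
#' (`repair`/`shunts`/`repair_plus_shunts`), `time` (years from definitive
#' surgery) and `event` (1 = death, 0 = censored). Missing optional
#' covariates are empty fields.
#'
#' Validation is structural only: every patient must carry at least one
#' known, non-obsolete ontology term, patient ids must be unique, and
#' survival times must be non-negative. Clinical inclusion rules (age
#' limits, record completeness) are assumed to have been applied upstream.
#' Alt ids are resolved to their primary term; terms unknown to the ontology
#' abort the load naming the offending row.
#'
#' @param path Path to the cohort TSV.
#' @param dag An `ontology_dag` the annotations must belong to.
#' @return An object of class `phenotype_cohort`: a list with
#'   `patients` (data.frame of covariates, one row per patient) and
#'   `term_sets` (named list, patient id -> character vector of term ids),
#'   plus the `dag` used for validation.
#' @export
load_cohort <- function(path, dag) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  as_cohort(tab, dag)
}

#' Build a cohort object from a data frame
#'
#' Same validation as [load_cohort()] but starting from an in-memory data
#' frame, which is how simulated cohorts enter the pipeline.
#'
#' @param tab Data frame with the cohort TSV columns.
#' @inheritParams load_cohort
#' @return A `phenotype_cohort`.
#' @export
as_cohort <- function(tab, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  need <- c("patient_id", "hpo_terms", "time", "event")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  pid <- as.character(tab$patient_id)
  if (anyDuplicated(pid)) {
    stop("duplicate patient_id: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  }

  term_sets <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    raw <- trimws(strsplit(as.character(tab$hpo_terms[i]), "|", fixed = TRUE)[[1]])
    raw <- raw[nzchar(raw)]
    if (!length(raw)) {
      stop("patient ", pid[i], " (row ", i,
           ") has no ontology terms; every patient must carry at least one")
    }
    obs <- intersect(raw, dag$obsolete)
    if (length(obs)) {
      stop("patient ", pid[i], " (row ", i, ") uses obsolete term(s): ",
           paste(obs, collapse = ", "))
    }
    bad <- raw[!(raw %in% dag$ids | raw %in% names(dag$alt_ids))]
    if (length(bad)) {
      stop("patient ", pid[i], " (row ", i, ") uses unknown term(s): ",
           paste(bad, collapse = ", "))
    }
    term_sets[[i]] <- sort(unique(vapply(raw, .resolve_term, "", dag = dag)))
  }
  names(term_sets) <- pid

  num <- function(col) {
    if (!col %in% names(tab)) return(rep(NA_real_, nrow(tab)))
    suppressWarnings(as.numeric(ifelse(tab[[col]] == "", NA, tab[[col]])))
  }
  chr <- function(col) {
    if (!col %in% names(tab)) return(rep(NA_character_, nrow(tab)))
    ifelse(tab[[col]] == "", NA_character_, as.character(tab[[col]]))
  }
  time <- num("time")
  event <- num("event")
  if (any(!is.na(time) & time < 0)) {
    stop("negative survival time for patient(s): ",
         paste(pid[!is.na(time) & time < 0], collapse = ", "))
  }
  if (any(!is.na(time) & is.na(event))) {
    stop("event indicator missing where time is present: ",
         paste(pid[!is.na(time) & is.na(event)], collapse = ", "))
  }

  patients <- data.frame(
    patient_id = pid,
    age_at_surgery = num("age_at_surgery"),
    sex = chr("sex"),
    bmi = num("bmi"),
    family_history = num("family_history"),
    surgery = chr("surgery"),
    time = time,
    event = event,
    stringsAsFactors = FALSE)

  structure(list(patients = patients, term_sets = term_sets, dag = dag),
            class = "phenotype_cohort")
}

#' @export
print.phenotype_cohort <- function(x, ...) {
  cat("phenotype_cohort:", nrow(x$patients), "patients,",
      length(unique(unlist(x$term_sets))), "distinct terms\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A `phenotype_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' Write a cohort back to the TSV interchange format
#' @param cohort A `phenotype_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  tab <- cohort$patients
  tab <- cbind(tab[, "patient_id", drop = FALSE],
               hpo_terms = vapply(cohort$term_sets[tab$patient_id],
                                  paste, "", collapse = "|"),
               tab[, setdiff(names(tab), "patient_id")])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Cohort term frequencies
#'
#' The frequency of a term is the fraction of patients annotated with it.
#' Under `closure_mode = "explicit"` a patient counts only for the terms it
#' carries verbatim; under `"propagated"` each patient's term set is first
#' closed under ontology ancestors (the true-path rule), so a parent's
#' frequency is at least that of any of its descendants. Propagated
#' frequencies are the ones used for information content and similarity;
#' explicit frequencies match descriptive prevalence tables.
#'
#' @param cohort A `phenotype_cohort`.
#' @param closure_mode `"explicit"` or `"propagated"`.
#' @return A data.frame with columns `term_id`, `name`, `count`,
#'   `frequency`, sorted by term id. Only terms with non-zero count appear.
#' @export
term_frequencies <- function(cohort, closure_mode = c("propagated", "explicit")) {
  closure_mode <- match.arg(closure_mode)
  stopifnot(inherits(cohort, "phenotype_cohort"))
  n <- n_patients(cohort)
  if (n == 0L) stop("empty cohort")
  sets <- cohort$term_sets
  if (closure_mode == "propagated") {
    sets <- lapply(sets, function(d) {
      sort(unique(unlist(cohort$dag$ancestors[d], use.names = FALSE)))
    })
  }
  counts <- table(unlist(sets, use.names = FALSE))
  term_id <- sort(names(counts))
  out <- data.frame(
    term_id = term_id,
    name = unname(cohort$dag$names[term_id]),
    count = as.integer(counts[term_id]),
    frequency = as.integer(counts[term_id]) / n,
    stringsAsFactors = FALSE)
  attr(out, "n_patients") <- n
  attr(out, "closure_mode") <- closure_mode
  out
}

#' Information content from cohort frequencies
#'
#' The information content of a term is the negative log of its annotation
#' frequency in the cohort, `IC(t) = -log p_t`. Rare terms are highly
#' informative; a term carried by every patient has zero information. The
#' natural log is the default (matching the ontology-similarity software
#' lineage); base 2 or 10 are available for reporting.
#'
#' Terms never observed in the cohort (frequency zero) get no information
#' content and therefore cannot contribute as common ancestors during
#' similarity computation.
#'
#' @param freqs A frequency table from [term_frequencies()].
#' @param base Log base: `"e"`, `"2"` or `"10"`.
#' @return An object of class `ic_table`: the input data.frame with an added
#'   `ic` column, carrying `n_patients`, `closure_mode` and `log_base`
#'   attributes.
#' @export
information_content <- function(freqs, base = c("e", "2", "10")) {
  base <- match.arg(base)
  stopifnot(is.data.frame(freqs), all(c("term_id", "frequency") %in% names(freqs)))
  if (any(freqs$frequency <= 0 | freqs$frequency > 1)) {
    drop <- freqs$frequency <= 0
    if (any(freqs$frequency > 1)) stop("frequencies must lie in (0, 1]")
    warning("dropping ", sum(drop), " zero-frequency term(s)")
    freqs <- freqs[!drop, , drop = FALSE]
  }
  logb <- switch(base, e = exp(1), `2` = 2, `10` = 10)
  freqs$ic <- -log(freqs$frequency, base = logb)
  attr(freqs, "log_base") <- base
  class(freqs) <- c("ic_table", "data.frame")
  freqs
}

#' Look up information content as a named vector
#' @param ic An `ic_table`.
#' @return Named numeric vector, term id -> IC; terms absent from the table
#'   are simply absent (treated as IC-less downstream).
#' @export
ic_vector <- function(ic) {
  stopifnot(inherits(ic, "ic_table"))
  stats::setNames(ic$ic, ic$term_id)
}

#' Per-patient term-count distribution
#'
#' Histogram of the number of (explicit) ontology terms per patient, plus
#' the median — the descriptive summary used to check that a cohort has the
#' expected annotation depth.
#'
#' @param cohort A `phenotype_cohort`.
#' @return List with `counts` (named integer vector: term count -> number of
#'   patients), `median`, `min` and `max`.
#' @export
terms_per_patient <- function(cohort) {
  stopifnot(inherits(cohort, "phenotype_cohort"))
  sizes <- lengths(cohort$term_sets)
  if (!length(sizes)) stop("empty cohort")
  list(counts = table(sizes),
       median = stats::median(sizes),
       min = min(sizes), max = max(sizes))
}

#' Export an IC table to TSV
#' @param ic An `ic_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ic_table <- function(ic, path) {
  utils::write.table(as.data.frame(ic), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
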