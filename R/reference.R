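#' Published reference counts for the emulated pulmonary-atresia cohort
#'
#' Summary counts transcribed from the published clinical-characteristics
#' table of the 648-patient pulmonary-atresia cohort whose shape the
#' simulator emulates: per-term presence counts overall and per phenotype
#' cluster (mapped onto the analogous toy-ontology terms), plus study-level
#' denominators (cluster sizes, enrolled/reached follow-up numbers, female
#' count). These are aggregate published numbers, not patient-level data.
#'
#' @return List with `terms` (data.frame: `variable`, `term_id`,
#'   `count_all`, `count_c1`..`count_c3`) and `study` (named numeric
#'   vector of denominators).
#' @export
pa_reference_counts <- function() {
  terms <- utils::read.delim(
    system.file("extdata", "pa_table1_counts.tsv", package = "phenoclust"),
    stringsAsFactors = FALSE)
  study_tab <- utils::read.delim(
    system.file("extdata", "pa_study_counts.tsv", package = "phenoclust"),
    stringsAsFactors = FALSE)
  list(terms = terms,
       study = stats::setNames(study_tab$value, study_tab$quantity))
}

#' Reconstruct a cohort matching published marginal term counts
#'
#' Builds a synthetic cohort of `n` patients whose explicit per-term
#' presence counts equal the supplied marginals exactly; which patients
#' carry which term is arbitrary (terms are laid out cyclically with
#' staggered offsets), so only marginal quantities — frequencies,
#' percentages, information content — are meaningful on the result. Every
#' patient additionally carries `base_term` so profiles are non-empty.
#'
#' @param term_counts Data.frame with columns `term_id` and `count`
#'   (presence counts out of `n`).
#' @param n Cohort size (the published denominator).
#' @param dag The `ontology_dag` the term ids live in.
#' @param n_female Optional female count; fills the `sex` column cyclically.
#' @param base_term Term id given to every patient (default: the toy
#'   pulmonary-atresia term).
#' @return A `phenotype_cohort` (no survival data: `time`/`event` are NA).
#' @export
marginal_cohort <- function(term_counts, n, dag, n_female = NULL,
                            base_term = "HP:9000203") {
  stopifnot(all(c("term_id", "count") %in% names(term_counts)),
            all(term_counts$count >= 0), all(term_counts$count <= n))
  sets <- rep(list(base_term), n)
  offset <- 0L
  for (i in seq_len(nrow(term_counts))) {
    cnt <- term_counts$count[i]
    if (cnt == 0) next
    who <- ((offset + seq_len(cnt) - 1L) %% n) + 1L
    for (j in who) sets[[j]] <- c(sets[[j]], term_counts$term_id[i])
    offset <- offset + 97L   # stagger so term blocks overlap arbitrarily
  }
  sex <- rep(NA_character_, n)
  if (!is.null(n_female)) {
    sex <- rep("male", n)
    sex[seq_len(n_female)] <- "female"
  }
  tab <- data.frame(
    patient_id = sprintf("M%04d", seq_len(n)),
    hpo_terms = vapply(sets, function(d) paste(sort(unique(d)),
                                               collapse = "|"), ""),
    sex = ifelse(is.na(sex), "", sex),
    time = "", event = "",
    stringsAsFactors = FALSE)
  as_cohort(tab, dag)
}
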