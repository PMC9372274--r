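# Shared fixtures, built in code at test time.

# write OBO text to a tempfile and return its path
write_obo <- function(stanzas) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", stanzas), path)
  path
}

# 5-term toy: root R; A, B is-a R; C is-a A; D is-a A and B (diamond)
toy_obo <- function() {
  write_obo(c(
    "[Term]", "id: T:R", "name: root", "",
    "[Term]", "id: T:A", "name: a", "is_a: T:R", "",
    "[Term]", "id: T:B", "name: b", "is_a: T:R", "",
    "[Term]", "id: T:C", "name: c", "is_a: T:A", "",
    "[Term]", "id: T:D", "name: d", "is_a: T:A", "is_a: T:B"))
}

toy_dag <- function() parse_obo(toy_obo())

fixture_dag <- local({
  dag <- NULL
  function() {
    if (is.null(dag)) {
      dag <<- parse_obo(system.file("extdata", "toy_cardiac.obo",
                                    package = "phenoclust"))
    }
    dag
  }
})

# build a cohort from a named list of term sets (plus optional covariates)
make_cohort <- function(term_sets, dag, time = NULL, event = NULL, ...) {
  n <- length(term_sets)
  tab <- data.frame(
    patient_id = names(term_sets),
    hpo_terms = vapply(term_sets, paste, "", collapse = "|"),
    time = if (is.null(time)) rep("", n) else as.character(time),
    event = if (is.null(event)) rep("", n) else as.character(event),
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) tab[[nm]] <- as.character(extra[[nm]])
  as_cohort(tab, dag)
}

# random DAG + random cohort over it, for property tests
random_dag <- function(n_terms, seed) {
  generate_ontology(n_terms, depth = sample(3:5, 1), seed = seed)$dag
}

random_cohort <- function(dag, n_patients, max_terms = 6) {
  sets <- lapply(seq_len(n_patients), function(i) {
    sort(sample(dag$ids, sample(seq_len(max_terms), 1)))
  })
  names(sets) <- sprintf("R%03d", seq_len(n_patients))
  make_cohort(sets, dag)
}
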