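#' Pipeline run configuration
#'
#' Collects every option of the end-to-end run; a run is reproducible from
#' its config alone, and the config (plus its MD5 hash) is serialized into
#' the output directory as part of the run manifest.
#'
#' @param ontology Path to the OBO ontology; `NULL` with `simulate = TRUE`
#'   uses the simulator's default.
#' @param cohort Path to a cohort TSV; ignored when `simulate = TRUE`.
#' @param out_dir Output directory for all artifacts.
#' @param simulate Generate the cohort with [generate_cohort()] instead of
#'   reading one.
#' @param log_base,closure_mode Information-content options (see
#'   [information_content()] and [term_frequencies()]).
#' @param k Number of clusters to cut.
#' @param linkage Agglomeration linkage (default `"complete"`).
#' @param ties Cox tie handling.
#' @param prevalence_univariate,prevalence_multivariate,alpha Variable
#'   selection thresholds for [cox_screen()].
#' @param seed Integer seed (drives the simulator when `simulate = TRUE`).
#' @return List of class `run_config`.
#' @export
run_config <- function(ontology = NULL, cohort = NULL, out_dir,
                       simulate = is.null(cohort),
                       log_base = "e", closure_mode = "propagated",
                       k = 3L, linkage = "complete", ties = "efron",
                       prevalence_univariate = 0.05,
                       prevalence_multivariate = 0.25,
                       alpha = 0.05, seed = 1L) {
  structure(list(ontology = ontology, cohort = cohort, out_dir = out_dir,
                 simulate = simulate, log_base = log_base,
                 closure_mode = closure_mode, k = as.integer(k),
                 linkage = linkage, ties = ties,
                 prevalence_univariate = prevalence_univariate,
                 prevalence_multivariate = prevalence_multivariate,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.stage_msg <- function(stage, t0, detail = "") {
  message(sprintf("[%s] %.2fs %s", stage,
                  as.numeric(Sys.time()) - t0, detail))
}

#' Run the full deep-phenotyping pipeline
#'
#' Sequences every stage end to end — cohort input (or simulation),
#' information content, patient similarity and distance matrices,
#' complete-linkage clustering and k-cut, cluster characterization tables,
#' Kaplan-Meier/log-rank survival comparison and the two-stage Cox screen —
#' and writes each intermediate as a plain-text artifact, so stages can be
#' inspected or re-consumed independently. A manifest records the config,
#' its hash and the package version; reruns with an identical config are
#' bit-identical.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly. Artifacts written:
#'   `ic_table.tsv`, `similarity_matrix.tsv` (+ `.json` sidecar),
#'   `distance_matrix.tsv`, `dendrogram.tsv`, `assignment.tsv`,
#'   `cluster_terms.tsv`, `cluster_covariates.tsv`, `km_curves.tsv`,
#'   `logrank.json`, `cox_univariate.tsv`, `cox_multivariate.tsv`,
#'   `manifest.json`, and for simulated runs `cohort.tsv`,
#'   `ground_truth.tsv`, `spec.json` and `recovery.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", config$out_dir, ")", call. = FALSE)
    })
  }

  # --- input ----------------------------------------------------------
  truth <- NULL
  if (config$simulate) {
    sim <- run_stage("simulate", {
      spec_args <- list(seed = config$seed)
      if (!is.null(config$ontology)) spec_args$ontology <- config$ontology
      generate_cohort(do.call(simulation_spec, spec_args),
                      dir = config$out_dir)
    })
    cohort <- sim$cohort
    truth <- sim$truth
    dag <- cohort$dag
    .stage_msg("simulate", t0, paste(n_patients(cohort), "patients"))
  } else {
    dag <- run_stage("ontology", parse_obo(config$ontology))
    cohort <- run_stage("cohort", load_cohort(config$cohort, dag))
    .stage_msg("cohort", t0, paste(n_patients(cohort), "patients"))
  }

  # --- information content -------------------------------------------
  ic <- run_stage("ic", {
    freqs <- term_frequencies(cohort, closure_mode = config$closure_mode)
    information_content(freqs, base = config$log_base)
  })
  write_ic_table(ic, file.path(config$out_dir, "ic_table.tsv"))
  .stage_msg("ic", t0, paste(nrow(ic), "terms"))

  # --- similarity / distance -----------------------------------------
  simmat <- run_stage("simmat", similarity_matrix(cohort, ic, dag))
  meta <- list(closure_mode = config$closure_mode,
               log_base = config$log_base, config_hash = hash)
  write_patient_matrix(simmat,
                       file.path(config$out_dir, "similarity_matrix.tsv"),
                       meta = meta)
  dmat <- run_stage("distance", to_distance(simmat))
  write_patient_matrix(dmat,
                       file.path(config$out_dir, "distance_matrix.tsv"),
                       meta = meta)
  .stage_msg("simmat", t0, sprintf("max_sim %.4f", simmat$max_sim))

  # --- clustering -----------------------------------------------------
  dend <- run_stage("cluster", complete_linkage(dmat, method = config$linkage))
  assignment <- run_stage("cluster", cut_tree(dend, config$k))
  write_dendrogram(dend, file.path(config$out_dir, "dendrogram.tsv"))
  write_assignment(assignment, file.path(config$out_dir, "assignment.tsv"))
  .stage_msg("cluster", t0,
             paste("sizes", paste(assignment$sizes, collapse = "/")))

  if (!is.null(truth)) {
    rec <- evaluate_recovery(assignment, truth)
    jsonlite::write_json(list(ari = rec$ari, config_hash = hash),
                         file.path(config$out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- characterization ----------------------------------------------
  run_stage("summarize", {
    utils::write.table(cluster_term_table(cohort, assignment),
                       file.path(config$out_dir, "cluster_terms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cluster_covariate_table(cohort, assignment),
                       file.path(config$out_dir, "cluster_covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  .stage_msg("summarize", t0)

  # --- survival -------------------------------------------------------
  run_stage("survive", {
    pats <- cohort$patients
    keep <- !is.na(pats$time)
    records <- pats[keep, c("time", "event")]
    groups <- assignment$labels[pats$patient_id][keep]
    write_km_curves(records, groups,
                    file.path(config$out_dir, "km_curves.tsv"))
    lr <- logrank_test(records, groups)
    jsonlite::write_json(
      list(chisq = lr$chisq, df = lr$df, p = lr$p, config_hash = hash),
      file.path(config$out_dir, "logrank.json"),
      auto_unbox = TRUE, digits = NA)
    cs <- cox_screen(cohort, assignment, ties = config$ties,
                     prevalence_univariate = config$prevalence_univariate,
                     prevalence_multivariate = config$prevalence_multivariate,
                     alpha = config$alpha)
    utils::write.table(cs$univariate,
                       file.path(config$out_dir, "cox_univariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(cs$multivariate),
                       file.path(config$out_dir, "cox_multivariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  .stage_msg("survive", t0)

  manifest <- list(package = "phenoclust",
                   version = as.character(utils::packageVersion("phenoclust")),
                   config = unclass(config), config_hash = hash)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
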