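#' Default per-cluster phenotype archetypes
#'
#' Term-inclusion probabilities for the three planted phenotype clusters of
#' the default simulation, defined over the packaged toy cardiac ontology.
#' The qualitative structure mirrors the deep-phenotyped pulmonary-atresia
#' setting the simulator emulates: a large cluster enriched for ventricular
#' septal defect, Fallot physiology, right ventricular hypertrophy and
#' aortopulmonary collaterals; a medium cluster enriched for hypoplastic
#' right heart, atrial septal defect and tricuspid disease; and a small
#' cluster enriched for single ventricle, dextrocardia and common atrium —
#' on top of shared high-frequency terms (the atresia term itself and the
#' ductus arteriosus analogue) and a tail of rare terms each confined to
#' one home cluster.
#'
#' The probabilities are deliberately disjoint-leaning so the planted
#' partition is recoverable by complete-linkage clustering of the
#' Resnik/best-match-average distance, which is governed by worst-case
#' pairs: each cluster carries one "defining lesion" marker at probability
#' 1 (guaranteeing a within-cluster similarity floor), supporting
#' signatures sit near 0.9 in the home cluster, and cross-cluster
#' probabilities of informative (low-frequency, high-IC) terms are held at
#' or below 0.01 — a single such leak carrier can otherwise bridge two
#' clusters and derail the agglomeration. Low-IC majority-cluster terms
#' tolerate larger leaks. Shared-term rates keep the per-patient term count
#' at a median near six within a 1-12 range.
#'
#' @return Data.frame with columns `term_id`, `p1`, `p2`, `p3`.
#' @export
default_archetypes <- function() {
  tab <- rbind(
    # term id            c1     c2     c3
    c("HP:9000203", 1.000, 1.000, 1.000),  # pulmonary artery atresia (all)
    c("HP:9000201", 0.900, 0.950, 0.300),  # ductus arteriosus (shared)
    c("HP:9000101", 1.000, 0.020, 0.050),  # VSD         defines cluster 1
    c("HP:9000202", 0.990, 0.010, 0.020),  # collaterals cluster 1
    c("HP:9000108", 0.900, 0.010, 0.050),  # TOF         cluster 1
    c("HP:9000105", 0.900, 0.020, 0.050),  # RVH         cluster 1
    c("HP:9000103", 0.350, 0.010, 0.010),  # foramen ovale, cluster 1 lean
    c("HP:9000107", 0.002, 1.000, 0.002),  # hypopl. right defines cluster 2
    c("HP:9000301", 0.002, 0.950, 0.002),  # tricusp regurg cluster 2
    c("HP:9000102", 0.010, 0.900, 0.010),  # ASD            cluster 2
    c("HP:9000302", 0.002, 0.600, 0.002),  # tricusp sten   cluster 2
    c("HP:9000303", 0.002, 0.550, 0.002),  # tricusp atres  cluster 2
    c("HP:9000109", 0.002, 0.002, 1.000),  # dextrocardia defines cluster 3
    c("HP:9000106", 0.002, 0.005, 0.950),  # single ventr   cluster 3
    c("HP:9000104", 0.002, 0.002, 0.900),  # common atrium  cluster 3
    c("HP:9000014", 0.002, 0.002, 0.650),  # abnormal AV connection, cluster 3
    c("HP:9000401", 0.002, 0.005, 0.550),  # RBBB           cluster 3
    c("HP:9000402", 0.002, 0.005, 0.600),  # abnormal T wave, cluster 3
    c("HP:9000206", 0.150, 0.000, 0.000),  # left SVC    rare, home c1
    c("HP:9000207", 0.060, 0.000, 0.000),  # TGA         rare, home c1
    c("HP:9000205", 0.060, 0.000, 0.000),  # right arch  rare, home c1
    c("HP:9000204", 0.000, 0.100, 0.000),  # PA stenosis rare, home c2
    c("HP:9000304", 0.000, 0.000, 0.050),  # mitral atresia rare, home c3
    c("HP:9000110", 0.000, 0.000, 0.050),  # mesocardia  rare, home c3
    c("HP:9000111", 0.000, 0.000, 0.080))  # AV canal    rare, home c3
  data.frame(term_id = tab[, 1],
             p1 = as.numeric(tab[, 2]),
             p2 = as.numeric(tab[, 3]),
             p3 = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

#' Simulation specification with study-shaped defaults
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults
#' describe the scenario the package is validated against: three latent
#' phenotype clusters of 522, 94 and 32 patients; term sets drawn per
#' cluster from [default_archetypes()] over the packaged toy ontology
#' (median about six terms per patient, capped at twelve); ages lognormal
#' around cluster medians of 2, 0.7 and 5.5 years; exponential survival
#' with a baseline (cluster 1) hazard of 0.024 per year — about 89%
#' five-year survival — doubled in clusters 2 and 3, with extra
#' proportional-hazards effects for the abnormal-atrioventricular-connection
#' term (hazard ratio 3.7) and the persistent-left-SVC term (2.3); and
#' censoring that mimics the follow-up pattern of a telephone-interview
#' study in which roughly half the cohort is reached late (uniform 5-13
#' years) and the rest are censored at an earlier last revisit (uniform
#' 0.25-5 years).
#'
#' @param cluster_sizes Integer vector of planted cluster sizes.
#' @param ontology Path to an OBO file; default is the packaged toy cardiac
#'   ontology.
#' @param archetypes Data.frame of per-cluster term-inclusion probabilities
#'   (`term_id`, then one `p<i>` column per cluster).
#' @param max_terms Upper bound for the per-patient term count; draws
#'   outside `[1, max_terms]` are resampled.
#' @param baseline_hazard Exponential event rate per year for cluster 1.
#' @param cluster_hazard_multipliers Per-cluster hazard multipliers.
#' @param term_betas Named numeric vector of log hazard ratios attached to
#'   term flags.
#' @param censoring List: `reached_prob`, `admin_window`, `dropout_window`
#'   (years).
#' @param age_meanlog,age_sdlog,female_prob,bmi_mean,bmi_sd,
#'   family_history_prob,surgery_probs Covariate distributions (per-cluster
#'   where vectors/matrices).
#' @param seed Integer seed; all randomness derives from it via named
#'   streams, so adding a stream never perturbs the others.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(
    cluster_sizes = c(522L, 94L, 32L),
    ontology = system.file("extdata", "toy_cardiac.obo",
                           package = "phenoclust"),
    archetypes = default_archetypes(),
    max_terms = 12L,
    baseline_hazard = 0.024,
    cluster_hazard_multipliers = c(1, 2, 2),
    term_betas = c("HP:9000014" = log(3.7), "HP:9000206" = log(2.3)),
    censoring = list(reached_prob = 0.512,
                     admin_window = c(5, 13),
                     dropout_window = c(0.25, 5)),
    age_meanlog = log(c(2, 0.71, 5.5)),
    age_sdlog = c(1.2, 1.4, 0.75),
    female_prob = c(0.4617, 0.4893, 0.25),
    bmi_mean = 15.8, bmi_sd = 4,
    family_history_prob = 0.01,
    surgery_probs = rbind(c(0.5345, 0.2874, 0.1782),
                          c(0.3723, 0.4043, 0.2234),
                          c(0.3125, 0.5000, 0.1875)),
    seed = 1L) {
  k <- length(cluster_sizes)
  pcols <- paste0("p", seq_len(k))
  stopifnot(k >= 1L, all(cluster_sizes >= 1L),
            all(pcols %in% names(archetypes)),
            all(unlist(archetypes[pcols]) >= 0),
            all(unlist(archetypes[pcols]) <= 1),
            length(cluster_hazard_multipliers) == k,
            baseline_hazard > 0)
  structure(list(cluster_sizes = as.integer(cluster_sizes),
                 ontology = ontology, archetypes = archetypes,
                 max_terms = as.integer(max_terms),
                 baseline_hazard = baseline_hazard,
                 cluster_hazard_multipliers = cluster_hazard_multipliers,
                 term_betas = term_betas, censoring = censoring,
                 age_meanlog = age_meanlog, age_sdlog = age_sdlog,
                 female_prob = female_prob, bmi_mean = bmi_mean,
                 bmi_sd = bmi_sd,
                 family_history_prob = family_history_prob,
                 surgery_probs = surgery_probs,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# One global integer seed feeds named substreams so each generation stage
# (terms, covariates, survival, censoring, ...) is independently
# reproducible. Kept below 2^31 - 1.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

#' Generate a random single-rooted toy ontology
#'
#' Builds a layered random DAG (one root, `depth` levels, average fan-out
#' `branching`), guarantees at least one multi-parent "diamond" node, and
#' serializes it as an OBO flat file that round-trips through [parse_obo()].
#' Output is byte-identical for a fixed seed.
#'
#' @param n_terms Total number of terms (`>= depth >= 2`).
#' @param depth Number of levels below which no term sits.
#' @param branching Unused beyond shaping the level allocation; levels are
#'   filled roughly geometrically.
#' @param seed Integer seed.
#' @param path Where to write the OBO file (default: tempfile).
#' @return List with `path` and the parsed `dag`.
#' @export
generate_ontology <- function(n_terms, depth = 3L, branching = 3L,
                              seed = 1L, path = tempfile(fileext = ".obo")) {
  if (n_terms < depth || depth < 2L) {
    stop("need n_terms >= depth >= 2 (got n_terms = ", n_terms,
         ", depth = ", depth, ")")
  }
  set.seed(stream_seed(seed, "ontology"))
  resample <- function(x, ...) x[sample.int(length(x), ...)]
  ids <- sprintf("HP:%07d", 8000000L + seq_len(n_terms))
  # allocate terms to levels: root alone, remaining levels non-empty
  lvl <- integer(n_terms)
  lvl[1] <- 1L
  rest <- 2:n_terms
  lvl[rest] <- sort(c(2:depth,
                      resample(2:depth, n_terms - depth, replace = TRUE)))
  parents <- vector("list", n_terms)
  parents[[1]] <- character(0)
  for (i in rest) {
    pool <- which(lvl == lvl[i] - 1L)
    parents[[i]] <- ids[resample(pool, 1L)]
  }
  # plant a diamond: a deepest-level term gets a second parent
  deep <- which(lvl == depth)
  pool <- which(lvl == depth - 1L)
  if (length(pool) >= 2L) {
    d <- deep[1L]
    others <- setdiff(pool, match(parents[[d]], ids))
    extra <- ids[resample(others, 1L)]
    parents[[d]] <- sort(unique(c(parents[[d]], extra)))
  }
  stanzas <- vapply(seq_len(n_terms), function(i) {
    isa <- if (length(parents[[i]])) {
      paste0("is_a: ", parents[[i]], "\n", collapse = "")
    } else ""
    paste0("[Term]\nid: ", ids[i], "\nname: synthetic term ", i, "\n", isa)
  }, "")
  writeLines(c("format-version: 1.2",
               "ontology: synthetic-random", "", stanzas), path, sep = "\n")
  list(path = path, dag = parse_obo(path))
}

#' Generate a synthetic deep-phenotyped cohort
#'
#' Draws a cohort under a [simulation_spec()]: per-cluster Bernoulli term
#' sets from the archetype probabilities (resampling draws outside the
#' allowed 1..`max_terms` size range), lognormal ages, cluster-specific sex
#' ratios and surgery-type frequencies, and exponential survival times with
#' hazard `baseline_hazard * multiplier[cluster] * exp(sum(beta * term
#' flag))`, right-censored by the two-component follow-up mechanism in the
#' spec. All randomness derives from `spec$seed`.
#'
#' @param spec A `simulation_spec`.
#' @param dir Optional output directory; when given, `cohort.tsv`,
#'   `ground_truth.tsv` and `spec.json` are written there.
#' @return List with `cohort` (a `phenotype_cohort`), `truth` (data.frame
#'   `patient_id`, `cluster` — the planted labels), and `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  dag <- parse_obo(spec$ontology)
  k <- length(spec$cluster_sizes)
  n <- sum(spec$cluster_sizes)
  cl <- rep(seq_len(k), spec$cluster_sizes)
  pid <- sprintf("P%04d", seq_len(n))
  terms <- spec$archetypes$term_id
  bad <- setdiff(terms, dag$ids)
  if (length(bad)) stop("archetype term(s) not in ontology: ",
                        paste(bad, collapse = ", "))
  probs <- as.matrix(spec$archetypes[paste0("p", seq_len(k))])

  # --- term sets ------------------------------------------------------
  set.seed(stream_seed(spec$seed, "terms"))
  term_sets <- vector("list", n)
  for (i in seq_len(n)) {
    p <- probs[, cl[i]]
    repeat {
      draw <- terms[stats::runif(length(terms)) < p]
      if (length(draw) >= 1L && length(draw) <= spec$max_terms) break
    }
    term_sets[[i]] <- sort(draw)
  }
  names(term_sets) <- pid

  # --- covariates -----------------------------------------------------
  set.seed(stream_seed(spec$seed, "covariates"))
  age <- pmin(pmax(stats::rlnorm(n, spec$age_meanlog[cl],
                                 spec$age_sdlog[cl]), 0.02), 18)
  sex <- ifelse(stats::runif(n) < spec$female_prob[cl], "female", "male")
  bmi <- pmin(pmax(stats::rnorm(n, spec$bmi_mean, spec$bmi_sd), 8), 45)
  fam <- as.integer(stats::runif(n) < spec$family_history_prob)
  surgery <- vapply(seq_len(n), function(i) {
    sample(c("repair", "shunts", "repair_plus_shunts"), 1L,
           prob = spec$surgery_probs[cl[i], ])
  }, "")

  # --- survival -------------------------------------------------------
  set.seed(stream_seed(spec$seed, "survival"))
  loghr <- rep(0, n)
  for (t in names(spec$term_betas)) {
    flag <- vapply(term_sets, function(d) t %in% d, logical(1))
    loghr <- loghr + spec$term_betas[[t]] * flag
  }
  rate <- spec$baseline_hazard * spec$cluster_hazard_multipliers[cl] *
    exp(loghr)
  t_event <- stats::rexp(n, rate)

  # --- censoring ------------------------------------------------------
  set.seed(stream_seed(spec$seed, "censoring"))
  reached <- stats::runif(n) < spec$censoring$reached_prob
  c_time <- ifelse(reached,
                   stats::runif(n, spec$censoring$admin_window[1],
                                spec$censoring$admin_window[2]),
                   stats::runif(n, spec$censoring$dropout_window[1],
                                spec$censoring$dropout_window[2]))
  time <- round(pmin(t_event, c_time), 4)
  event <- as.integer(t_event <= c_time)

  patients <- data.frame(
    patient_id = pid,
    age_at_surgery = round(age, 2), sex = sex, bmi = round(bmi, 1),
    family_history = fam, surgery = surgery,
    time = time, event = event, stringsAsFactors = FALSE)
  cohort <- structure(list(patients = patients, term_sets = term_sets,
                           dag = dag),
                      class = "phenotype_cohort")
  truth <- data.frame(patient_id = pid, cluster = cl,
                      stringsAsFactors = FALSE)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(dir, "cohort.tsv"))
    utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ser <- spec
    ser$surgery_probs <- as.data.frame(ser$surgery_probs)
    jsonlite::write_json(unclass(ser), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, truth = truth, spec = spec)
}

#' Score cluster recovery against planted labels
#'
#' Compares an inferred [cut_tree()] assignment with the simulator's ground
#' truth using the adjusted Rand index (chance-corrected pair agreement;
#' 1 = identical partitions, about 0 = random) plus the confusion table.
#'
#' @param assignment A `cluster_assignment`.
#' @param truth Ground-truth data.frame (`patient_id`, `cluster`) from
#'   [generate_cohort()].
#' @return List with `ari` and `confusion` (inferred x planted table).
#' @export
evaluate_recovery <- function(assignment, truth) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!setequal(names(assignment$labels), truth$patient_id)) {
    stop("assignment and ground truth cover different patients")
  }
  inferred <- assignment$labels[truth$patient_id]
  list(ari = mclust::adjustedRandIndex(inferred, truth$cluster),
       confusion = table(inferred = inferred, planted = truth$cluster))
}
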