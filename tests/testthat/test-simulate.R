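small_spec <- function(seed = 1, ...) {
  simulation_spec(cluster_sizes = c(60L, 25L, 15L), seed = seed, ...)
}

test_that("generated ontologies are valid, rooted, diamonded, and round-trip", {
  gen <- generate_ontology(25, depth = 4, seed = 3)
  dag <- gen$dag
  expect_length(dag$roots, 1L)
  expect_true(any(lengths(dag$parents) >= 2))   # at least one diamond
  # round-trip: reparsing the serialized file reproduces ids and edges
  dag2 <- parse_obo(gen$path)
  expect_identical(dag$ids, dag2$ids)
  expect_identical(dag$parents, dag2$parents)
  # byte-identical serialization under a fixed seed
  p2 <- generate_ontology(25, depth = 4, seed = 3)$path
  expect_identical(readLines(gen$path), readLines(p2))
  expect_error(generate_ontology(3, depth = 5), "n_terms >= depth")
})

test_that("generated cohorts honor the simulation spec: sizes, term bounds, determinism", {
  spec <- small_spec(seed = 11)
  sim <- generate_cohort(spec)
  expect_equal(n_patients(sim$cohort), 100L)
  expect_equal(as.integer(table(sim$truth$cluster)), c(60L, 25L, 15L))
  sizes <- lengths(sim$cohort$term_sets)
  expect_true(all(sizes >= 1 & sizes <= spec$max_terms))
  expect_true(all(sim$cohort$patients$time >= 0))
  expect_true(all(sim$cohort$patients$event %in% 0:1))
  # same seed, byte-identical cohort TSV; different seed differs
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  generate_cohort(small_spec(seed = 5), dir = d1)
  generate_cohort(small_spec(seed = 5), dir = d2)
  generate_cohort(small_spec(seed = 6), dir = d3)
  f <- function(d) readLines(file.path(d, "cohort.tsv"))
  expect_identical(f(d1), f(d2))
  expect_false(identical(f(d1), f(d3)))
  expect_true(file.exists(file.path(d1, "spec.json")))
  expect_true(file.exists(file.path(d1, "ground_truth.tsv")))
})

test_that("per-patient term-count median sits near six at the default spec", {
  meds <- vapply(1:8, function(s) {
    terms_per_patient(generate_cohort(simulation_spec(seed = s))$cohort)$median
  }, 0)
  expect_true(all(meds >= 5 & meds <= 7))
})

test_that("survival generator matches its exponential target without censoring", {
  spec <- simulation_spec(
    cluster_sizes = c(10000L),
    archetypes = data.frame(term_id = "HP:9000203", p1 = 1),
    cluster_hazard_multipliers = 1,
    term_betas = numeric(0),
    censoring = list(reached_prob = 1, admin_window = c(1e6, 1e6 + 1),
                     dropout_window = c(0.1, 1)),
    seed = 31)
  sim <- generate_cohort(spec)
  km <- km_estimate(sim$cohort$patients[, c("time", "event")])
  med <- km_readout(km)$median
  expect_equal(med, log(2) / spec$baseline_hazard, tolerance = 0.02)
})

test_that("null hazards leave the planted clusters indistinguishable in survival", {
  spec <- simulation_spec(cluster_sizes = c(80L, 80L, 80L),
                          cluster_hazard_multipliers = c(1, 1, 1),
                          term_betas = numeric(0), seed = 17)
  sim <- generate_cohort(spec)
  p <- sim$cohort$patients
  lr <- logrank_test(p[, c("time", "event")], sim$truth$cluster)
  expect_gt(lr$p, 0.01)
})

test_that("recovery scoring equals the pair-count oracle and behaves at the ends", {
  labels <- setNames(rep(1:3, c(30, 20, 10)), sprintf("P%04d", 1:60))
  asg <- structure(list(k = 3L, labels = labels,
                        sizes = c(30L, 20L, 10L)),
                   class = "cluster_assignment")
  truth <- data.frame(patient_id = names(labels),
                      cluster = unname(labels))
  expect_equal(evaluate_recovery(asg, truth)$ari, 1)
  # one swapped patient out of 60: closed-form pair counting
  flipped <- labels
  flipped[60] <- 1L
  asg2 <- structure(list(k = 3L, labels = flipped,
                         sizes = as.integer(table(flipped))),
                    class = "cluster_assignment")
  expect_equal(evaluate_recovery(asg2, truth)$ari,
               oracle_ari(flipped, truth$cluster), tolerance = 1e-12)
  # random labels hover near zero
  set.seed(28)
  aris <- replicate(20, {
    rnd <- setNames(sample(1:3, 600, TRUE), sprintf("P%04d", 1:600))
    a <- structure(list(k = 3L, labels = rnd,
                        sizes = as.integer(table(rnd))),
                   class = "cluster_assignment")
    evaluate_recovery(a, data.frame(patient_id = names(rnd),
                                    cluster = rep(1:3, each = 200)))$ari
  })
  expect_lt(max(abs(aris)), 0.05)
  expect_error(evaluate_recovery(asg, data.frame(patient_id = "zz",
                                                 cluster = 1)),
               "different patients")
})

test_that("fully disjoint archetype blocks are recovered perfectly by the pipeline", {
  arch <- data.frame(
    term_id = c("HP:9000101", "HP:9000108", "HP:9000107", "HP:9000301",
                "HP:9000106", "HP:9000109"),
    p1 = c(1, 0.8, 0, 0, 0, 0),
    p2 = c(0, 0, 1, 0.8, 0, 0),
    p3 = c(0, 0, 0, 0, 1, 0.8))
  sim <- generate_cohort(small_spec(seed = 4, archetypes = arch))
  co <- sim$cohort
  ic <- information_content(term_frequencies(co, "propagated"))
  asg <- cut_tree(complete_linkage(to_distance(
    similarity_matrix(co, ic, co$dag))), 3)
  expect_equal(evaluate_recovery(asg, sim$truth)$ari, 1)
})
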