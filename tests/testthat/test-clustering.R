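test_that("complete linkage merges forced small configurations correctly", {
  # two points: single merge at their distance
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- complete_linkage(d2)
  expect_equal(h2$height, 3)
  # three points d(AB)=1 d(AC)=2 d(BC)=3: merge (A,B) at 1, then C at 3
  d3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h3 <- complete_linkage(d3)
  expect_equal(h3$height, c(1, 3))
  expect_error(complete_linkage(matrix(0, 1, 1)), "at least two")
  bad <- d3; bad[1, 2] <- 5
  expect_error(complete_linkage(bad), "symmetric")
})

test_that("merge heights match the naive O(n^3) agglomeration oracle", {
  set.seed(15)
  for (i in 1:10) {
    D <- random_dissimilarity(15)
    fit <- complete_linkage(D)
    expect_equal(fit$height, oracle_complete_linkage_heights(D),
                 tolerance = 1e-12)
    expect_true(all(diff(fit$height) >= 0))  # monotone linkage
  }
})

test_that("cut_tree yields k clusters renumbered by descending size", {
  set.seed(8)
  D <- random_dissimilarity(20)
  rownames(D) <- colnames(D) <- sprintf("p%02d", 1:20)
  dend <- complete_linkage(D)
  expect_equal(cut_tree(dend, 1)$sizes, 20L)
  expect_equal(sort(names(cut_tree(dend, 1)$labels)), sort(rownames(D)))
  kn <- cut_tree(dend, 20)
  expect_equal(kn$sizes, rep(1L, 20))
  for (k in 2:6) {
    a <- cut_tree(dend, k)
    expect_equal(sum(a$sizes), 20L)
    expect_equal(a$sizes, sort(a$sizes, decreasing = TRUE))
    expect_equal(as.integer(table(a$labels)), a$sizes)
  }
  expect_error(cut_tree(dend, 0))
  expect_error(cut_tree(dend, 21))
})

test_that("per-term cluster tables cross-tabulate, test and format correctly", {
  dag <- toy_dag()
  # balanced fixture: identical prevalence in both clusters
  sets <- c(lapply(1:10, function(i) if (i <= 5) c("T:C", "T:B") else "T:B"),
            lapply(1:10, function(i) if (i <= 5) c("T:C", "T:B") else "T:B"))
  names(sets) <- sprintf("p%02d", 1:20)
  co <- make_cohort(sets, dag)
  asg <- structure(list(k = 2L,
                        labels = setNames(rep(1:2, each = 10), names(sets)),
                        sizes = c(10L, 10L)),
                   class = "cluster_assignment")
  tab <- cluster_term_table(co, asg, fisher_threshold = 0)
  rowC <- tab[tab$term_id == "T:C", ]
  expect_equal(rowC$count_c1, 5L)
  expect_equal(rowC$count_c2, 5L)
  expect_equal(rowC$pct_c1, 50)
  expect_equal(rowC$p, 1)                       # chi-square statistic 0
  expect_equal(rowC$test, "chisq")
  # term in everyone is untestable
  expect_equal(tab[tab$term_id == "T:B", ]$test, "none")
  # per-term cluster counts sum to the overall count
  expect_equal(tab$count, tab$count_c1 + tab$count_c2)
})

test_that("small observed cells trigger Fisher's exact test matching dhyper enumeration", {
  dag <- toy_dag()
  sets <- c(lapply(1:12, function(i) if (i <= 8) c("T:C", "T:B") else "T:B"),
            lapply(1:12, function(i) if (i <= 2) c("T:C", "T:B") else "T:B"))
  names(sets) <- sprintf("p%02d", 1:24)
  co <- make_cohort(sets, dag)
  asg <- structure(list(k = 2L,
                        labels = setNames(rep(1:2, each = 12), names(sets)),
                        sizes = c(12L, 12L)),
                   class = "cluster_assignment")
  tab <- cluster_term_table(co, asg)     # min cell 2 < 10 -> fisher
  rowC <- tab[tab$term_id == "T:C", ]
  expect_equal(rowC$test, "fisher")
  # exhaustive hypergeometric enumeration over tables with fixed margins
  probs <- dhyper(0:10, 10, 14, 12)
  p_exact <- sum(probs[probs <= dhyper(8, 10, 14, 12) * (1 + 1e-7)])
  expect_equal(rowC$p, p_exact, tolerance = 1e-10)
})

test_that("the published VSD 2x3 split is flagged highly heterogeneous", {
  ref <- pa_reference_counts()
  vsd <- ref$terms[ref$terms$variable == "VSD", ]
  sizes <- unname(ref$study[c("n_cluster1", "n_cluster2", "n_cluster3")])
  present <- as.numeric(vsd[c("count_c1", "count_c2", "count_c3")])
  tab <- rbind(present, sizes - present)
  # min observed cell (9) < 10: published rule says Fisher, both agree here
  expect_lt(fisher.test(tab, workspace = 2e6)$p.value, 0.001)
  expect_equal(oracle_chisq_stat(tab),
               unname(chisq.test(tab, correct = FALSE)$statistic))
})

test_that("chi-square statistics equal the textbook sum over (O-E)^2/E", {
  set.seed(12)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 30) + 10, 2, 3)
    expect_equal(unname(chisq.test(tab, correct = FALSE)$statistic),
                 oracle_chisq_stat(tab), tolerance = 1e-10)
  }
})

test_that("continuous covariates route to ANOVA or rank tests as distributions dictate", {
  dag <- toy_dag()
  n <- 150
  sets <- rep(list(c("T:C")), n)
  names(sets) <- sprintf("p%03d", 1:n)
  cl <- rep(1:3, each = 50)
  set.seed(42)
  # identical normal groups -> ANOVA, p near 1-ish; shifted groups -> tiny p
  age_null <- rnorm(n, 10, 2)
  age_shift <- rnorm(n, 10 + 2 * 2 * (cl == 3), 2)  # 2 SD shift in group 3
  bmi_skew <- exp(rnorm(n, 2, 0.8))                 # lognormal: rank test
  co <- make_cohort(sets, dag, age_at_surgery = age_null, bmi = bmi_skew)
  asg <- structure(list(k = 3L, labels = setNames(cl, names(sets)),
                        sizes = as.integer(table(cl))),
                   class = "cluster_assignment")
  tab <- cluster_covariate_table(co, asg)
  # the gate must agree with independently computed per-group Shapiro tests
  route <- function(x) {
    ps <- tapply(round(as.numeric(co$patients[[x]]), 10), cl,
                 function(g) shapiro.test(g)$p.value)
    if (all(ps > 0.05)) "anova" else "kruskal"
  }
  expect_equal(tab$test[tab$variable == "age_at_surgery"],
               route("age_at_surgery"))
  expect_gt(tab$p[tab$variable == "age_at_surgery"], 0.05)
  expect_equal(tab$test[tab$variable == "bmi"], "kruskal")
  expect_equal(route("bmi"), "kruskal")  # lognormal really is rejected

  co2 <- make_cohort(sets, dag, age_at_surgery = age_shift)
  tab2 <- cluster_covariate_table(co2, asg, covariates = "age_at_surgery")
  expect_lt(tab2$p, 0.001)
})

test_that("the rank test statistic equals direct rank arithmetic (two groups)", {
  set.seed(19)
  x <- c(rnorm(20), rnorm(25, 1))
  g <- rep(1:2, c(20, 25))
  expect_equal(unname(kruskal.test(x, g)$statistic),
               oracle_kruskal_stat(x, g), tolerance = 1e-12)
})
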