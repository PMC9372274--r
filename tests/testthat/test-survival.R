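test_that("Kaplan-Meier estimates match closed forms and the literal product oracle", {
  # no events: survival stays at 1
  km0 <- km_estimate(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)))
  expect_true(all(km0$surv == 1))
  # n = 4, one death at t = 1: S(1) = 3/4
  km1 <- km_estimate(data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 0, 0)))
  expect_equal(km1$surv[km1$time == 1], 3 / 4)
  # mixed fixture with ties (censoring at an event time stays at risk)
  rec <- data.frame(time = c(1, 1, 2, 2, 3, 4, 4, 5, 6, 7),
                    event = c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0))
  km <- km_estimate(rec)
  for (tt in c(1, 2, 4, 6, 7)) {
    expect_equal(km_readout(km, at = tt)$surv_at,
                 oracle_km(rec$time, rec$event, tt), tolerance = 1e-12)
  }
  # invariant to record ordering
  perm <- sample(nrow(rec))
  km_perm <- km_estimate(rec[perm, ])
  expect_equal(km_perm$time, km$time)
  expect_equal(km_perm$surv, km$surv)
  expect_equal(km_perm$n_risk, km$n_risk)
  expect_error(km_estimate(data.frame(time = -1, event = 1)), "non-negative")
})

test_that("log-rank is zero on mirrored groups and invariant to relabeling", {
  rec <- data.frame(time = rep(c(1, 2, 3, 4, 5), 2),
                    event = rep(c(1, 0, 1, 1, 0), 2))
  g <- rep(1:2, each = 5)
  lr <- logrank_test(rec, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_equal(lr$df, 1L)
  set.seed(2)
  rec2 <- data.frame(time = rexp(40), event = rbinom(40, 1, 0.7))
  g2 <- rep(1:2, each = 20)
  expect_equal(logrank_test(rec2, g2)$chisq,
               logrank_test(rec2, 3 - g2)$chisq)
  expect_error(logrank_test(rec2, rep(1, 40)), "two groups")
  expect_error(logrank_test(data.frame(time = 1:4, event = rep(0, 4)),
                            rep(1:2, 2)), "zero events")
})

test_that("two-group log-rank equals the squared standardized O-E score", {
  set.seed(6)
  for (i in 1:5) {
    n <- 60
    rec <- data.frame(time = round(rexp(n, 0.3), 2),
                      event = rbinom(n, 1, 0.8))
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(rec$event) == 0) next
    o <- oracle_logrank2(rec$time, rec$event, g)
    expect_equal(logrank_test(rec, g)$chisq, o$chisq, tolerance = 1e-8)
  }
})

test_that("Cox regression recovers null and true effects and maximizes the partial likelihood", {
  set.seed(123)
  # null covariate: |beta| < 3 SE
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1)
  c0 <- rexp(n, 0.05)
  rec <- data.frame(time = pmin(t, c0), event = as.integer(t <= c0))
  fit <- cox_fit(rec, data.frame(x = x))
  expect_lt(abs(fit$coef[1]), 3 * fit$se[1])
  expect_equal(fit$hr, exp(fit$coef))
  expect_equal(fit$ci_low, exp(fit$coef - 1.96 * fit$se))
  # no-ties fixture: estimate maximizes the literal partial likelihood
  set.seed(7)
  n <- 40
  x2 <- rbinom(n, 1, 0.5)
  t2 <- rexp(n, 0.1 * exp(0.8 * x2))        # continuous: no ties
  rec2 <- data.frame(time = t2, event = 1L)
  b_hat <- cox_fit(rec2, data.frame(x = x2))$coef[1]
  b_grid <- optimize(function(b) oracle_cox_pl(b, t2, rec2$event, x2),
                     c(-3, 3), maximum = TRUE)$maximum
  expect_equal(b_hat, b_grid, tolerance = 1e-4)
  expect_lte(oracle_cox_pl(b_grid, t2, rec2$event, x2) -
               oracle_cox_pl(b_hat, t2, rec2$event, x2), 1e-6)
  expect_error(cox_fit(rec2, data.frame(x = rep(1, n))), "constant")
})

test_that("parameter recovery across effect sizes and censoring levels is unbiased", {
  set.seed(456)
  for (b_true in c(0, log(2))) {
    for (cens_rate in c(0.05, 0.12)) {
      est <- replicate(40, {
        n <- 300
        x <- rbinom(n, 1, 0.5)
        t <- rexp(n, 0.1 * exp(b_true * x))
        cc <- rexp(n, cens_rate)
        rec <- data.frame(time = pmin(t, cc), event = as.integer(t <= cc))
        cox_fit(rec, data.frame(x = x))$coef[1]
      })
      expect_lt(abs(mean(est) - b_true), 0.1)
    }
  }
})

test_that("variable selection applies the prevalence and significance rules", {
  dag <- fixture_dag()
  n <- 100
  sets <- lapply(seq_len(n), function(i) {
    s <- "HP:9000203"                               # universal
    if (i <= 30) s <- c(s, "HP:9000101")            # 30% term
    if (i <= 8) s <- c(s, "HP:9000104")             # 8% term
    if (i <= 3) s <- c(s, "HP:9000304")             # 3% (rare) term
    s
  })
  names(sets) <- sprintf("p%03d", seq_len(n))
  set.seed(1)
  co <- make_cohort(sets, dag,
                    time = round(rexp(n, 0.1), 3), event = rbinom(n, 1, 0.6),
                    age_at_surgery = round(runif(n, 0, 18), 1),
                    sex = sample(c("female", "male"), n, TRUE),
                    surgery = sample(c("repair", "shunts"), n, TRUE))
  asg <- structure(list(k = 2L,
                        labels = setNames(rep(1:2, each = 50), names(sets)),
                        sizes = c(50L, 50L)),
                   class = "cluster_assignment")
  uni <- select_variables(co, asg, "univariate")
  expect_true(all(c("cluster", "age_at_surgery", "sex", "surgery",
                    "HP:9000101", "HP:9000104") %in% uni))
  expect_false("HP:9000304" %in% uni)     # below the 5% screen
  expect_false("HP:9000203" %in% uni)     # universal: constant, untestable

  # multivariate: >25% terms enter regardless; rare terms only if significant
  ures <- data.frame(variable = c("HP:9000104", "HP:9000304"),
                     p = c(0.80, 0.01))
  multi <- select_variables(co, asg, "multivariate",
                            univariate_results = ures)
  expect_true("HP:9000101" %in% multi)    # 30% > 25% prevalence route
  expect_false("HP:9000104" %in% multi)   # 8%, not significant
  expect_true("HP:9000304" %in% multi)    # rare but significant route
  expect_error(select_variables(co, asg, "multivariate"), "univariate")
})
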