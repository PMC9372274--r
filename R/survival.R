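#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function from right-censored
#' records, `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`.
#' Censored observations tied with an event time are handled events-first
#' (they remain in the risk set for that event time). Estimation is
#' delegated to [survival::survfit()]; the return value is a tidy step
#' table.
#'
#' @param records Data.frame with numeric `time` (>= 0) and `event`
#'   (1 = death, 0 = censored) columns.
#' @param conf.int Confidence level for the optional band (default 0.95).
#' @return Data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `lower`, `upper`, preceded by
#'   the `t = 0` row where survival is 1.
#' @export
km_estimate <- function(records, conf.int = 0.95) {
  .check_records(records)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1, conf.int = conf.int)
  sm <- summary(fit, censored = TRUE)
  out <- data.frame(time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, n_censor = sm$n.censor,
                    surv = sm$surv, lower = sm$lower, upper = sm$upper)
  rbind(data.frame(time = 0, n_risk = nrow(records), n_event = 0,
                   n_censor = 0, surv = 1, lower = 1, upper = 1),
        out[out$time > 0, , drop = FALSE])
}

.check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (!nrow(records)) stop("no survival records")
  if (any(is.na(records$time)) || any(records$time < 0)) {
    stop("survival times must be non-negative and non-missing")
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be binary (1 = death, 0 = censored)")
  }
  invisible(records)
}

#' Median survival and survival probability at a landmark time
#'
#' Convenience readouts from a Kaplan-Meier table: the estimated survival
#' probability at `at` years (the step value in force at that time) and the
#' median survival time, `NA` when the curve never falls below 0.5.
#'
#' @param km A Kaplan-Meier table from [km_estimate()].
#' @param at Landmark time in years.
#' @return List with `surv_at` and `median`.
#' @export
km_readout <- function(km, at = 5) {
  idx <- which(km$time <= at)
  surv_at <- if (length(idx)) km$surv[max(idx)] else 1
  below <- which(km$surv <= 0.5)
  med <- if (length(below)) km$time[min(below)] else NA_real_
  list(surv_at = surv_at, median = med)
}

#' Log-rank test across survival groups
#'
#' Standard observed-minus-expected log-rank comparison of `k >= 2` groups
#' with hypergeometric variance over the shared risk sets, referred to the
#' chi-square distribution with `k - 1` degrees of freedom. Delegated to
#' [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @param groups Factor or vector of group labels, one per record.
#' @return List with `chisq`, `df`, `p` and the per-group
#'   observed/expected table.
#' @export
logrank_test <- function(records, groups) {
  .check_records(records)
  groups <- as.factor(groups)
  if (length(groups) != nrow(records)) stop("one group label per record")
  if (nlevels(droplevels(groups)) < 2L) stop("need at least two groups")
  if (sum(records$event) == 0) stop("log-rank undefined with zero events")
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ groups)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       table = data.frame(group = levels(droplevels(groups)),
                          n = as.vector(sd$n), observed = sd$obs,
                          expected = sd$exp))
}

#' Cox proportional-hazards regression
#'
#' Semiparametric hazard regression: covariates multiply a common baseline
#' hazard by `exp(beta * x)`, with `beta` estimated by maximum partial
#' likelihood ([survival::coxph()], Newton-Raphson). Standard errors come
#' from the inverse observed information; confidence intervals are reported
#' as `exp(coef +/- 1.96 * SE)` and p-values are two-sided Wald tests.
#'
#' @inheritParams km_estimate
#' @param design Data.frame of covariates aligned with `records` (numeric
#'   columns and factors both allowed; factors are dummy-coded against their
#'   first level).
#' @param ties Tie handling: `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_result`: data.frame with one row per
#'   model term — `variable`, `coef`, `se`, `hr`, `ci_low`, `ci_high`, `p`
#'   — with the fitted [survival::coxph] object in attribute `fit`.
#' @export
cox_fit <- function(records, design, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_records(records)
  stopifnot(is.data.frame(design), nrow(design) == nrow(records))
  constant <- vapply(design, function(x) length(unique(x[!is.na(x)])) < 2L,
                     logical(1))
  if (any(constant)) {
    stop("covariate(s) constant across records: ",
         paste(names(design)[constant], collapse = ", "))
  }
  if (sum(records$event) < ncol(design)) {
    warning("fewer events (", sum(records$event),
            ") than covariates (", ncol(design), "); estimates unstable")
  }
  dat <- cbind(records[, c("time", "event")], design)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ ., data = dat, ties = ties,
    control = survival::coxph.control(eps = 1e-10, iter.max = 100))
  s <- summary(fit)
  co <- s$coefficients
  out <- data.frame(variable = rownames(co),
                    coef = co[, "coef"],
                    se = co[, "se(coef)"],
                    hr = exp(co[, "coef"]),
                    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "ties") <- ties
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Variable selection for the univariate and multivariate Cox models
#'
#' Implements the two-stage screening rule used for prognostic-marker
#' discovery in deep-phenotyped cohorts. The univariate stage tests, one at
#' a time: the phenotype cluster, the demographic covariates (age at
#' surgery, sex, BMI, family history), the surgery type, and every ontology
#' term with cohort prevalence above `prevalence_univariate` (default 5%).
#' The multivariate model then pools the variables significant in the
#' univariate screen (`p < alpha`) with the cluster, demographics, surgery
#' type, and every term with prevalence above `prevalence_multivariate`
#' (default 25%) — so a common term enters the multivariate model even when
#' its univariate test was null, while a rare term can enter only through
#' univariate significance.
#'
#' @param cohort A `phenotype_cohort`.
#' @param assignment A `cluster_assignment`.
#' @param stage `"univariate"` or `"multivariate"`.
#' @param univariate_results For the multivariate stage, the data.frame
#'   returned by [cox_screen()]'s univariate pass (columns `variable`, `p`).
#' @param prevalence_univariate,prevalence_multivariate Term-prevalence
#'   cutoffs (fractions).
#' @param alpha Univariate significance threshold feeding the multivariate
#'   roster.
#' @return Character vector of variable names (covariate names and term
#'   ids).
#' @export
select_variables <- function(cohort, assignment,
                             stage = c("univariate", "multivariate"),
                             univariate_results = NULL,
                             prevalence_univariate = 0.05,
                             prevalence_multivariate = 0.25,
                             alpha = 0.05) {
  stage <- match.arg(stage)
  freqs <- term_frequencies(cohort, closure_mode = "explicit")
  demo <- intersect(c("age_at_surgery", "sex", "bmi", "family_history",
                      "surgery"),
                    names(cohort$patients)[!vapply(cohort$patients,
                                                   function(x) all(is.na(x)),
                                                   logical(1))])
  if (stage == "univariate") {
    terms <- freqs$term_id[freqs$frequency > prevalence_univariate]
    out <- c("cluster", demo, terms)
  } else {
    if (is.null(univariate_results)) {
      stop("multivariate selection needs the univariate results")
    }
    signif <- univariate_results$variable[
      !is.na(univariate_results$p) & univariate_results$p < alpha]
    terms <- freqs$term_id[freqs$frequency > prevalence_multivariate]
    out <- unique(c("cluster", demo, terms, signif))
  }
  # drop variables constant in this cohort (untestable)
  out <- out[vapply(out, function(v) {
    x <- .cox_column(cohort, assignment, v, stage)
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1))]
  if (!length(out)) stop("variable selection produced an empty set")
  out
}

# Build the numeric/factor column for one selected variable.
# The cluster enters the univariate screen as a single ordinal score (the
# published univariable treatment) and the multivariate model as a factor
# with the smallest cluster as reference level.
.cox_column <- function(cohort, assignment, v, stage) {
  pid <- cohort$patients$patient_id
  if (v == "cluster") {
    cl <- assignment$labels[pid]
    if (stage == "univariate") return(as.numeric(cl))
    return(stats::relevel(factor(cl), ref = as.character(assignment$k)))
  }
  if (v %in% names(cohort$patients)) {
    x <- cohort$patients[[v]]
    if (v == "sex") return(as.numeric(x == "female"))
    if (v == "surgery") return(factor(x))
    return(x)
  }
  # otherwise an ontology term: presence flag
  as.numeric(vapply(cohort$term_sets[pid], function(d) v %in% d, logical(1)))
}

#' Univariate screen and multivariate Cox model for a clustered cohort
#'
#' Runs the full prognostic-factor workflow: one univariate Cox model per
#' selected variable, then a single multivariate model over the pooled
#' roster from [select_variables()]. Records with missing time are dropped;
#' records missing a covariate are dropped from the models that use it.
#'
#' @inheritParams select_variables
#' @param ties Passed to [cox_fit()].
#' @return List with `univariate` (data.frame: variable, coef, hr, ci, p)
#'   and `multivariate` (a `cox_result`), plus `variables` (the multivariate
#'   roster).
#' @export
cox_screen <- function(cohort, assignment, ties = "efron",
                       prevalence_univariate = 0.05,
                       prevalence_multivariate = 0.25, alpha = 0.05) {
  keep <- !is.na(cohort$patients$time)
  records <- cohort$patients[keep, c("time", "event")]
  sub <- function(x) x[keep]

  uni_vars <- select_variables(cohort, assignment, "univariate",
                               prevalence_univariate = prevalence_univariate)
  uni <- do.call(rbind, lapply(uni_vars, function(v) {
    x <- sub(.cox_column(cohort, assignment, v, "univariate"))
    ok <- !is.na(x)
    fit <- suppressWarnings(
      cox_fit(records[ok, , drop = FALSE],
              stats::setNames(data.frame(x = x[ok]), v), ties = ties))
    data.frame(variable = v, coef = fit$coef[1], se = fit$se[1],
               hr = fit$hr[1], ci_low = fit$ci_low[1],
               ci_high = fit$ci_high[1], p = fit$p[1],
               stringsAsFactors = FALSE)
  }))

  multi_vars <- select_variables(
    cohort, assignment, "multivariate", univariate_results = uni,
    prevalence_univariate = prevalence_univariate,
    prevalence_multivariate = prevalence_multivariate, alpha = alpha)
  design <- as.data.frame(
    lapply(stats::setNames(multi_vars, multi_vars), function(v) {
      sub(.cox_column(cohort, assignment, v, "multivariate"))
    }), check.names = FALSE)
  ok <- stats::complete.cases(design)
  multi <- suppressWarnings(cox_fit(records[ok, ], design[ok, , drop = FALSE],
                                    ties = ties))
  list(univariate = uni, multivariate = multi, variables = multi_vars)
}

#' Write Kaplan-Meier curves per group to TSV
#' @inheritParams logrank_test
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_km_curves <- function(records, groups, path) {
  groups <- as.factor(groups)
  tabs <- lapply(levels(groups), function(g) {
    km <- km_estimate(records[groups == g, , drop = FALSE])
    cbind(group = g, km)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
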