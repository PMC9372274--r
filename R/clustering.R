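#' Complete-linkage hierarchical clustering of a patient distance matrix
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximal distance between any two of their members. Complete linkage is
#' monotone, so merge heights never decrease. The agglomeration itself is
#' delegated to [stats::hclust()]; this wrapper validates the dissimilarity
#' (symmetry, zero diagonal) and keeps the patient ids as leaf labels.
#'
#' @param dist A `patient_distance` from [to_distance()], or a plain
#'   symmetric matrix with zero diagonal.
#' @param method Linkage passed through to [stats::hclust()]; the pipeline
#'   default (and the only one exercised by the package's own checks) is
#'   `"complete"`.
#' @return An [stats::hclust] tree (`merge`, `height`, `order`, `labels`).
#' @export
complete_linkage <- function(dist, method = "complete") {
  m <- if (inherits(dist, "patient_distance")) dist$dist else as.matrix(dist)
  if (nrow(m) < 2L) stop("need at least two patients to cluster")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(m < 0)) stop("distances must be non-negative")
  stats::hclust(stats::as.dist(m), method = method)
}

#' Cut a dendrogram into k phenotype clusters
#'
#' Cuts the tree at the height yielding exactly `k` clusters and renumbers
#' the labels by descending cluster size, so cluster 1 is always the largest
#' (ties in size keep the original cut order). The size ordering makes
#' cluster indices comparable across runs and seeds.
#'
#' @param dend An [stats::hclust] tree from [complete_linkage()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return An object of class `cluster_assignment`: list with `k`, `labels`
#'   (named integer vector, patient id -> cluster in `1..k`) and `sizes`.
#' @export
cut_tree <- function(dend, k) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$order)
  if (k < 1L || k > n) stop("k must lie in 1..", n)
  raw <- stats::cutree(dend, k = k)
  sz <- table(raw)
  # renumber by descending size; ties by original label for stability
  new_of_old <- stats::setNames(seq_len(k),
                                names(sort(sz, decreasing = TRUE)))
  labels <- stats::setNames(as.integer(new_of_old[as.character(raw)]),
                            names(raw))
  structure(list(k = k, labels = labels,
                 sizes = as.integer(table(labels))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: k =", x$k, "sizes:",
      paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Per-term cluster characterization table
#'
#' For every ontology term observed in the cohort, tabulates presence
#' against cluster membership (a 2 x k contingency table), reports per
#' cluster counts and percentages, and tests homogeneity across clusters
#' with the Pearson chi-square test — switching to Fisher's exact test
#' whenever any observed cell of the table falls below `fisher_threshold`
#' (default 10, the conventional small-count guard). P-values are
#' two-sided.
#'
#' @param cohort A `phenotype_cohort`.
#' @param assignment A `cluster_assignment` covering the cohort.
#' @param fisher_threshold Minimum observed cell count below which the
#'   chi-square test is replaced by Fisher's exact test.
#' @return Data.frame, one row per term: `term_id`, `name`, `count`,
#'   `pct`, `count_c<i>`/`pct_c<i>` per cluster, `test`
#'   (`chisq`/`fisher`) and `p`. Percentages are rounded to two decimals.
#' @export
cluster_term_table <- function(cohort, assignment, fisher_threshold = 10) {
  stopifnot(inherits(cohort, "phenotype_cohort"),
            inherits(assignment, "cluster_assignment"))
  pid <- cohort$patients$patient_id
  if (!all(pid %in% names(assignment$labels))) {
    stop("assignment does not cover the cohort")
  }
  cl <- assignment$labels[pid]
  k <- assignment$k
  n <- length(pid)
  terms <- sort(unique(unlist(cohort$term_sets, use.names = FALSE)))

  rows <- lapply(terms, function(t) {
    has <- vapply(cohort$term_sets[pid], function(d) t %in% d, logical(1))
    tab <- table(factor(has, levels = c(TRUE, FALSE)),
                 factor(cl, levels = seq_len(k)))
    cnt <- as.integer(tab["TRUE", ])
    use_fisher <- any(tab < fisher_threshold)
    res <- if (all(has) || !any(has)) {
      list(test = "none", p = NA_real_)
    } else if (use_fisher) {
      p <- tryCatch(
        stats::fisher.test(tab, workspace = 2e6)$p.value,
        error = function(e) tryCatch(
          stats::fisher.test(tab, workspace = 2e8)$p.value,
          error = function(e2)
            stats::fisher.test(tab, hybrid = TRUE,
                               simulate.p.value = FALSE,
                               workspace = 2e8)$p.value))
      list(test = "fisher", p = p)
    } else {
      list(test = "chisq",
           p = stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    out <- data.frame(term_id = t, name = unname(cohort$dag$names[t]),
                      count = sum(cnt), pct = round(100 * sum(cnt) / n, 2),
                      stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      out[[paste0("count_c", i)]] <- cnt[i]
      out[[paste0("pct_c", i)]] <- round(100 * cnt[i] / sum(cl == i), 2)
    }
    out$test <- res$test
    out$p <- res$p
    out
  })
  do.call(rbind, rows)
}

#' Continuous-covariate cluster comparison
#'
#' Compares continuous covariates (age at surgery, BMI, ...) across
#' clusters. Each covariate is screened for per-group normality with the
#' Shapiro-Wilk test at `alpha_normal`; when every group looks normal the
#' comparison is a one-way ANOVA and the summary is mean +/- SD, otherwise a
#' Kruskal-Wallis rank test with median (IQR) summaries. Covariates with
#' fewer than two non-missing values in any cluster are skipped.
#'
#' @inheritParams cluster_term_table
#' @param covariates Character vector of numeric columns in
#'   `cohort$patients` to compare.
#' @param alpha_normal Shapiro-Wilk significance level gating ANOVA vs the
#'   rank test.
#' @return Data.frame: `variable`, `test` (`anova`/`kruskal`), `p`, and a
#'   formatted `summary_c<i>` per cluster plus `summary_all`.
#' @export
cluster_covariate_table <- function(cohort, assignment,
                                    covariates = c("age_at_surgery", "bmi"),
                                    alpha_normal = 0.05) {
  stopifnot(inherits(cohort, "phenotype_cohort"),
            inherits(assignment, "cluster_assignment"))
  pid <- cohort$patients$patient_id
  cl <- factor(assignment$labels[pid], levels = seq_len(assignment$k))
  rows <- list()
  for (v in covariates) {
    x <- cohort$patients[[v]]
    if (is.null(x)) next
    ok <- !is.na(x)
    if (any(tapply(ok, cl, sum) < 2)) next
    groups <- split(x[ok], cl[ok])
    normal <- vapply(groups, function(g) {
      if (length(g) < 3 || length(unique(g)) < 3) return(FALSE)
      stats::shapiro.test(g[seq_len(min(length(g), 5000))])$p.value > alpha_normal
    }, logical(1))
    if (all(normal)) {
      fit <- stats::oneway.test(x[ok] ~ cl[ok], var.equal = TRUE)
      test <- "anova"; p <- fit$p.value
      fmt <- function(g) sprintf("%.2f ± %.2f", mean(g), stats::sd(g))
    } else {
      fit <- stats::kruskal.test(x[ok], cl[ok])
      test <- "kruskal"; p <- fit$p.value
      fmt <- function(g) {
        q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
      }
    }
    row <- data.frame(variable = v, test = test, p = p,
                      summary_all = fmt(x[ok]), stringsAsFactors = FALSE)
    for (i in seq_along(groups)) {
      row[[paste0("summary_c", i)]] <- fmt(groups[[i]])
    }
    rows[[v]] <- row
  }
  if (!length(rows)) stop("no usable continuous covariates")
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Export a dendrogram merge table and an assignment table
#' @param dend An [stats::hclust] tree.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dend, path) {
  tab <- data.frame(left = dend$merge[, 1], right = dend$merge[, 2],
                    height = dend$height)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dendrogram
#' @param assignment A `cluster_assignment`.
#' @export
write_assignment <- function(assignment, path) {
  tab <- data.frame(patient_id = names(assignment$labels),
                    cluster = unname(assignment$labels))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
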