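# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (loops, literal formulas) and share no code
# with the package internals they check.

# reflexive ancestor closure by breadth-first upward walk
oracle_ancestors <- function(dag, t) {
  seen <- character(0)
  frontier <- t
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
  }
  sort(seen)
}

# Resnik term similarity: max IC over the ancestor intersection
oracle_term_sim <- function(dag, icv, s, t) {
  ca <- intersect(oracle_ancestors(dag, s), oracle_ancestors(dag, t))
  vals <- icv[ca[ca %in% names(icv)]]
  if (!length(vals)) 0 else max(vals)
}

# literal evaluation of the best-match-average double sum
oracle_set_sim <- function(dag, icv, Da, Db) {
  fwd <- 0
  for (s in Da) fwd <- fwd + max(vapply(Db, function(t)
    oracle_term_sim(dag, icv, s, t), 0))
  bwd <- 0
  for (s in Db) bwd <- bwd + max(vapply(Da, function(t)
    oracle_term_sim(dag, icv, s, t), 0))
  fwd / (2 * length(Da)) + bwd / (2 * length(Db))
}

# naive O(n^3) complete-linkage agglomeration: rescan all cluster pairs at
# every step; returns the sorted sequence of merge heights
oracle_complete_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# product-limit estimator evaluated literally, term by term
oracle_km <- function(time, event, at) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ev_times[ev_times <= at]) {
    n_i <- sum(time >= tt)          # censored at tt stay at risk (events first)
    d_i <- sum(time == tt & event == 1)
    s <- s * (1 - d_i / n_i)
  }
  s
}

# two-group log-rank O, E, V by explicit risk-set hypergeometrics
oracle_logrank2 <- function(time, event, grp) {
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in ev_times) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & grp == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chisq = (O - E)^2 / V)
}

# textbook chi-square statistic from a contingency table
oracle_chisq_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Kruskal-Wallis H by direct rank arithmetic (with tie correction)
oracle_kruskal_stat <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Cox partial log-likelihood for a single covariate, no ties (Breslow =
# Efron in that case), evaluated by explicit risk-set loops
oracle_cox_pl <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# adjusted Rand index from pair counts
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(m) sum(m * (m - 1) / 2)
  nij <- comb2(tab)
  ai <- comb2(rowSums(tab))
  bj <- comb2(colSums(tab))
  np <- comb2(sum(tab))
  expected <- ai * bj / np
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# random dissimilarity matrix (symmetric, zero diagonal, continuous values
# so agglomeration ties have probability zero)
random_dissimilarity <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 10)
  m + t(m)
}
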