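# Independent oracles used across test files. Each recomputes the target
# quantity from first principles (summation, enumeration, hand formulas),
# never through the package code paths it checks.

# upper binomial tail by term-by-term summation (log-scale terms so large n
# does not overflow choose())
binom_tail_oracle <- function(g, n, p0) {
  if (g == 0) return(1)
  k <- g:n
  sum(exp(lchoose(n, k) + k * log(p0) + (n - k) * log1p(-p0)))
}

# BH step-up: sort, multiply by n/rank, enforce monotonicity from the bottom
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (no ties assumed)
mw_exact_oracle <- function(case, ref) {
  pooled <- c(case, ref)
  n1 <- length(case)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  pu <- mean(us <= u_obs)
  po <- mean(us >= u_obs)
  min(1, 2 * min(pu, po))
}

# two-group unweighted log-rank chi-square from the observed/expected table
logrank_oracle <- function(times, events, group) {
  group <- as.integer(factor(group))
  ev_times <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d_j <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1L)
    o_minus_e <- o_minus_e + d1 - d_j * n1 / n_j
    if (n_j > 1)
      v <- v + d_j * (n1 / n_j) * (1 - n1 / n_j) * (n_j - d_j) / (n_j - 1)
  }
  o_minus_e^2 / v
}

# hypergeometric upper tail P(X >= k) by direct summation
hyper_tail_oracle <- function(k, white, black, drawn) {
  kk <- k:min(white, drawn)
  sum(choose(white, kk) * choose(black, drawn - kk)) /
    choose(white + black, drawn)
}

# two-sided Fisher exact p: sum of table probabilities <= observed
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1), 0)
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

# adjusted Rand index from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# editing matrix built straight from g/cov count matrices
em_from_counts <- function(g, cov) {
  lev <- ifelse(!is.na(cov) & cov > 0, g / cov, NA_real_)
  editing_matrix(lev, g, cov)
}

# map cluster labels onto truth by majority overlap; returns relabelled vector
map_to_truth <- function(labels, truth) {
  tab <- table(labels[labels > 0], truth[labels > 0])
  mapping <- colnames(tab)[apply(tab, 1, which.max)]
  out <- rep(NA_integer_, length(labels))
  out[labels > 0] <- as.integer(mapping[match(labels[labels > 0],
                                              rownames(tab))])
  out
}
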