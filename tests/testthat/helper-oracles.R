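# Independent oracles used across the suite. Each is written directly from
# textbook definitions (enumeration, closed forms, resampling) and never
# calls the implementation it checks.

# exact two-sided permutation p of the Mann-Whitney U statistic: enumerate
# every assignment of the pooled values to group sizes (n1, n2)
oracle_exact_ranksum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  mu <- n1 * (length(pooled) - n1) / 2
  idx <- utils::combn(length(pooled), n1)
  U_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Spearman r for tie-free data via the classical d^2 formula
oracle_spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Monte-Carlo permutation p for |Spearman r| (midranks), B shuffles
oracle_perm_spearman_p <- function(x, y, B = 2e4, seed = 42) {
  set.seed(seed)
  rx <- rank(x)
  ry <- rank(y)
  r_obs <- abs(cor(rx, ry))
  r_perm <- replicate(B, abs(cor(rx, sample(ry))))
  mean(r_perm >= r_obs - 1e-12)
}

# hypergeometric upper tail by direct pmf summation
oracle_hyper_upper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# residuals of simple linear regression by the closed-form slope/intercept
oracle_simple_ols_resid <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  y - (a + b * x)
}

# hand step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
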