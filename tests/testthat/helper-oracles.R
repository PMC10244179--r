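# Independent small-sample oracles: exact enumeration of rank-based tests
# and permutation enumeration for the Kruskal-Wallis statistic. These stay
# deliberately brute-force and independent of the implementations they check.

# Two-sided exact rank-sum p-value by enumerating all assignments of the
# pooled ranks to the first sample.
exact_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n)])
  combos <- utils::combn(n + m, n)
  w_all <- apply(combos, 2L, function(idx) sum(rk[idx]))
  mu <- n * (n + m + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Two-sided exact one-sample signed-rank p-value by enumerating all 2^n sign
# assignments (zeros dropped, as in the signed-rank convention).
exact_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% rk)
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# Tie-corrected Kruskal-Wallis H statistic (same definition as
# stats::kruskal.test).
kw_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  rk <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(rk, groups, function(r) length(r) * mean(r)^2)) -
    3 * (n + 1)
  ties <- table(rk)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation p-value for the Kruskal-Wallis statistic with three
# equal groups of size k (enumerates all distinct label assignments).
perm_kw_p_3groups <- function(values, k) {
  n <- 3L * k
  stopifnot(length(values) == n)
  h_obs <- kw_h(values, rep(1:3, each = k))
  idx <- seq_len(n)
  h_all <- numeric(0)
  g1 <- utils::combn(idx, k)
  for (c1 in seq_len(ncol(g1))) {
    rest <- setdiff(idx, g1[, c1])
    g2 <- utils::combn(rest, k)
    for (c2 in seq_len(ncol(g2))) {
      lab <- integer(n)
      lab[g1[, c1]] <- 1L
      lab[g2[, c2]] <- 2L
      lab[lab == 0L] <- 3L
      h_all <- c(h_all, kw_h(values, lab))
    }
  }
  mean(h_all >= h_obs - 1e-12)
}

# Gaussian profile helper used across dendritic-event tests.
gauss_profile <- function(x, center, sigma, amp = 1) {
  amp * exp(-(x - center)^2 / (2 * sigma^2))
}
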