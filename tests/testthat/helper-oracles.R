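# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately avoid the code paths (and where
# possible the library calls) they validate.

# Exact two-sided rank-sum p-value by enumerating all assignments of the
# pooled ranks to the first sample (no ties assumed).
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of sample a
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Welch t statistic, degrees of freedom and two-sided p from the
# closed-form formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Trapezoidal integral by direct summation over consecutive pairs.
oracle_trapz <- function(z, r) {
  s <- 0
  for (i in seq_len(length(z) - 1)) {
    s <- s + (z[i + 1] - z[i]) * (r[i] + r[i + 1]) / 2
  }
  s
}

# One-way ANOVA F statistic from the textbook sums of squares.
oracle_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  k <- length(unique(groups))
  n <- length(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}
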