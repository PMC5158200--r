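# Independent definitional oracles, deliberately coded from first principles
# (normal equations, t CDF, enumeration) rather than through the package or
# the same stats wrappers it calls.

# Least squares of y on x via the normal equations; returns slope and the
# fitted value at x0.
oracle_ls <- function(x, y, x0) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(slope = beta[2], at = beta[1] + beta[2] * x0)
}

# Paired t from the defining formula and the t CDF.
oracle_paired_t <- function(a, b) {
  d <- b - a
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Squared Pearson correlation from the covariance formula.
oracle_r2 <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my))^2 / (sum((x - mx)^2) * sum((y - my)^2))
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all draws
# of size n from a universe of `bg` genes of which `K` are in the family.
oracle_hyper <- function(k, K, bg, n) {
  draws <- combn(bg, n)
  in_family <- draws <= K     # label genes 1..K as the family
  mean(colSums(in_family) >= k)
}

# Reverse complement through Biostrings (independent implementation).
oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# A small zero-noise count matrix with integer-friendly parameters so that
# rounding is exact, plus its generating config.
zero_noise_matrix <- function(n_mirnas = 12, planted_fc = NULL,
                              conditions = c("crxnrl", "shA"),
                              baseline = rep(c(50, 120, 300), length.out = n_mirnas),
                              seed = 5) {
  cfg <- sim_config(
    n_mirnas = n_mirnas, noise_cv = 0, sample_cv = 0,
    conditions = conditions, planted_fc = planted_fc,
    baseline_abund = baseline, seed = seed
  )
  simulate_ncounter(cfg)
}
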