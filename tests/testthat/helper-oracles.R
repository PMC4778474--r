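# Independent oracles used to cross-check the package implementation.
# These deliberately take the naive route (base R, explicit pair
# construction) and never call package internals.

# Spearman via base R: rank-then-Pearson with midranks
oracle_spearman <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  stats::cor(x[ok], y[ok], method = "spearman")
}

# Naive lagged cross-correlation: for each lag, explicitly build the pair
# lists month by month, then rank-and-correlate.
oracle_lagged_xcorr <- function(va, vb, lags, alignment) {
  rho <- n_pairs <- setNames(rep(NA_real_, length(lags)), lags)
  for (j in seq_along(lags)) {
    k <- lags[j]
    xs <- ys <- numeric(0)
    for (m in 1:12) {
      m2 <- m + k
      if (alignment == "circular") m2 <- ((m2 - 1) %% 12) + 1
      if (m2 < 1 || m2 > 12) next
      if (is.na(va[m]) || is.na(vb[m2])) next
      xs <- c(xs, va[m]); ys <- c(ys, vb[m2])
    }
    n_pairs[j] <- length(xs)
    if (length(xs) >= 3 && stats::sd(rank(xs)) > 0 && stats::sd(rank(ys)) > 0)
      rho[j] <- stats::cor(xs, ys, method = "spearman")
  }
  list(rho = rho, n_pairs = n_pairs)
}

# classical one-way ANOVA F via lm/anova
oracle_anova_f <- function(y, g) {
  stats::anova(stats::lm(y ~ factor(g)))[1, "F value"]
}

# brute-force two-step pooled mean: per-month mean of per-group means
oracle_pooled_mean <- function(df, month) {
  gm <- tapply(df$value[df$month == month],
               df$group[df$month == month], mean)
  mean(gm)
}
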