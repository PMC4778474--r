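#' Permutation test for a calendar-month effect on repeated measures
#'
#' Tests whether a variable varies by calendar month using the
#' within-individual centred values. The statistic is the one-way F ratio of
#' the centred values grouped by month (between-month mean square over
#' within-month mean square). Its null distribution is built by permuting the
#' month labels **within each individual**: this destroys any seasonal
#' alignment while preserving each individual's set of values (and its mean
#' of zero), so stable between-individual differences — however large —
#' cannot masquerade as seasonality. Under the null of no month effect and
#' exchangeable within-individual values the test is exact.
#'
#' The p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, whose smallest attainable
#' value is `1/(n_perm + 1)`. No degrees of freedom are attached to the
#' statistic: it is calibrated by permutation, not by an F reference
#' distribution, and is reported descriptively.
#'
#' @param panel a longitudinal panel data.frame (see [gen_panel()]).
#' @param variable `"gcm"` or `"weight"`.
#' @param n_perm number of within-individual label permutations (>= 99).
#' @param seed integer seed; results are reproducible given it.
#' @return An object of class `month_effect_test`: `statistic`,
#'   `per_month_effect` (mean centred value per calendar month; its
#'   observation-weighted mean is 0), `p_perm`, `n_perm`, `seed`, `n_obs`,
#'   `n_individuals`, `months_present`.
#' @export
month_effect_test <- function(panel, variable, n_perm = 10000, seed = 1) {
  if (!is_count(n_perm, 99)) stopf("n_perm must be an integer >= 99")
  n_perm <- as.integer(n_perm)
  cen <- center_within_individual(panel, variable)
  d <- cen$panel[order(cen$panel$id), , drop = FALSE]
  y <- d$value
  g <- as.integer(d$month)
  months_present <- sort(unique(g))
  if (length(months_present) < 2L)
    stopf("month effect needs >= 2 calendar months represented, got %d",
          length(months_present))
  N <- length(y)
  gf <- match(g, months_present)          # compact group index 1..k
  k <- length(months_present)
  cnt <- tabulate(gf, k)                  # invariant under within-id permutation
  sum_y <- sum(y); sum_y2 <- sum(y * y)
  f_from_sums <- function(S) {
    ssb <- sum(S * S / cnt) - sum_y^2 / N
    sst <- sum_y2 - sum_y^2 / N
    ssw <- sst - ssb
    (ssb / (k - 1)) / (ssw / (N - k))
  }
  S_obs <- as.numeric(rowsum(y, gf))
  stat_obs <- f_from_sums(S_obs)

  id <- d$id
  idn <- match(id, unique(id))            # rows are id-sorted; integer blocks
  ge <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_perm)) {
      ord <- order(idn, stats::runif(N))  # random order within each id block
      S <- as.numeric(rowsum(y, gf[ord]))
      if (f_from_sums(S) >= stat_obs - 1e-12) count <- count + 1L
    }
    count
  })
  p_perm <- (1 + ge) / (1 + n_perm)

  eff <- rep(NA_real_, 12L)
  eff[months_present] <- S_obs / cnt
  structure(list(
    variable = variable,
    statistic = stat_obs,
    per_month_effect = setNames(eff, MONTH_ABB),
    p_perm = p_perm,
    n_perm = n_perm,
    seed = as.integer(seed),
    n_obs = N,
    n_individuals = length(unique(id)),
    months_present = months_present,
    dropped_individuals = cen$dropped
  ), class = "month_effect_test")
}

#' @export
print.month_effect_test <- function(x, ...) {
  cat(sprintf("Permutation month-effect test on centred %s\n", x$variable))
  cat(sprintf("  %d observations from %d individuals, %d months represented\n",
              x$n_obs, x$n_individuals, length(x$months_present)))
  cat(sprintf("  F-like statistic = %.3f, permutation p = %.4g (n_perm = %d)\n",
              x$statistic, x$p_perm, x$n_perm))
  invisible(x)
}

#' Percent contrast between two groups with a bootstrap interval
#'
#' Computes `100 * (mean_a - mean_b) / mean_b` on **per-individual means**
#' (one value per animal, so repeated monthly measures do not inflate the
#' effective sample size), with a seeded percentile bootstrap over
#' individuals. This is the form in which sex and age contrasts are usually
#' quoted, e.g. "adult males are x% heavier than adult females".
#'
#' @param panel a longitudinal panel data.frame.
#' @param variable `"gcm"` or `"weight"`.
#' @param grouping_field the column defining the groups (e.g. `"sex"`).
#' @param level_a,level_b the two levels to contrast; `level_b` is the
#'   reference.
#' @param subset optional logical vector over panel rows restricting the data
#'   first (e.g. adults only).
#' @param n_boot bootstrap replicates (default 1999).
#' @param conf interval coverage (default 0.95).
#' @param seed integer seed.
#' @return An object of class `group_contrast`: `estimate` (percent),
#'   `ci` (length-2 percentile interval), `n_a`, `n_b`, plus metadata.
#' @export
group_contrast <- function(panel, variable, grouping_field, level_a, level_b,
                           subset = NULL, n_boot = 1999, conf = 0.95, seed = 1) {
  if (!grouping_field %in% names(panel))
    stopf("grouping field '%s' absent from panel", grouping_field)
  d <- panel[panel$variable == variable, , drop = FALSE]
  if (!is.null(subset)) d <- d[subset[panel$variable == variable], , drop = FALSE]
  da <- d[d[[grouping_field]] == level_a, , drop = FALSE]
  db <- d[d[[grouping_field]] == level_b, , drop = FALSE]
  if (!nrow(da)) stopf("no observations with %s = '%s'", grouping_field, level_a)
  if (!nrow(db)) stopf("no observations with %s = '%s'", grouping_field, level_b)
  ma <- as.numeric(tapply(da$value, da$id, mean))
  mb <- as.numeric(tapply(db$value, db$id, mean))
  est <- 100 * (mean(ma) - mean(mb)) / mean(mb)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ba <- ma[sample.int(length(ma), replace = TRUE)]
      bb <- mb[sample.int(length(mb), replace = TRUE)]
      100 * (mean(ba) - mean(bb)) / mean(bb)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  structure(list(
    variable = variable, grouping_field = grouping_field,
    level_a = level_a, level_b = level_b,
    estimate = est,
    ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
    conf = conf, n_a = length(ma), n_b = length(mb),
    n_boot = as.integer(n_boot), seed = as.integer(seed)
  ), class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("%s: %s '%s' vs '%s' (per-individual means, n = %d vs %d)\n",
              x$variable, x$grouping_field, x$level_a, x$level_b, x$n_a, x$n_b))
  cat(sprintf("  %+.1f%% (%d%% bootstrap CI %.1f to %.1f)\n",
              x$estimate, round(100 * x$conf), x$ci[1], x$ci[2]))
  invisible(x)
}
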