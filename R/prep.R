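#' Within-individual centering of a longitudinal panel
#'
#' Decomposes each individual's repeated measures into the individual's own
#' mean over its observed months and month-specific deviations from it. The
#' deviations isolate within-subject (seasonal) variation from stable
#' between-subject differences, so a month effect on the centred values
#' cannot be an artifact of which individuals happened to be sampled when.
#' The default sign convention is the standard deviation-from-own-mean,
#' `value - individual mean`; `negate = TRUE` flips it (the mirrored
#' convention is sometimes quoted; the sign affects only the direction, not
#' the magnitude, of downstream correlations).
#'
#' Individuals with fewer than 2 observations of the variable carry no
#' within-individual information and are dropped with a warning (they remain
#' usable for monthly means).
#'
#' @param panel a longitudinal panel data.frame (see [gen_panel()] for the
#'   schema).
#' @param variable `"gcm"` or `"weight"`.
#' @param negate flip the sign of the centred values.
#' @return a list with components `panel` (the centred observations, `value`
#'   holding the deviation), `individual_means` (data.frame `id`, `mean`,
#'   `n_obs`), and `dropped` (ids excluded for having < 2 observations).
#' @examples
#' p <- data.frame(id = "a", sex = "female", age_group = "17-44", camp = "c",
#'                 month = 1:3, variable = "gcm", value = c(10, 12, 14))
#' center_within_individual(p, "gcm")$panel$value  # -2 0 2
#' @export
center_within_individual <- function(panel, variable, negate = FALSE) {
  d <- panel[panel$variable == variable, , drop = FALSE]
  if (!nrow(d)) stopf("variable '%s' absent from panel", variable)
  n_by_id <- table(d$id)
  keep_ids <- names(n_by_id)[n_by_id >= 2L]
  dropped <- setdiff(names(n_by_id), keep_ids)
  if (length(dropped))
    warning(sprintf("dropping %d individual(s) with < 2 observations of '%s': %s",
                    length(dropped), variable, paste(dropped, collapse = ", ")),
            call. = FALSE)
  d <- d[d$id %in% keep_ids, , drop = FALSE]
  if (!nrow(d)) stopf("no individual has >= 2 observations of '%s'", variable)
  mu <- tapply(d$value, d$id, mean)
  cen <- d$value - as.numeric(mu[d$id])
  if (negate) cen <- -cen
  out <- d
  out$value <- cen
  list(
    panel = out,
    individual_means = data.frame(id = names(mu), mean = as.numeric(mu),
                                  n_obs = as.integer(n_by_id[names(mu)]),
                                  row.names = NULL),
    dropped = dropped
  )
}

#' Monthly means per group and a group-balanced pooled series
#'
#' Computes, for each level combination of the grouping fields, the
#' arithmetic mean of the variable per calendar month, and a pooled series
#' defined as the **unweighted mean of the per-group monthly means**. The
#' balanced pooling matters: if group composition shifts between months
#' (e.g. more males weighed in some months), a raw grand mean would fold
#' those composition shifts into the apparent seasonal profile, whereas the
#' balanced mean controls for sex and age by construction. Months with no
#' data in any group propagate as missing; they are never imputed.
#'
#' @param panel a longitudinal panel data.frame.
#' @param variable `"gcm"` or `"weight"`.
#' @param grouping character subset of `c("sex", "age_group", "camp")`.
#' @return a list with `groups` (named list of [monthly_series()], one per
#'   group, `n_contributing` = individuals contributing per month) and
#'   `pooled` (a `monthly_series`; `n_contributing` = number of groups with
#'   data that month).
#' @export
monthly_group_means <- function(panel, variable, grouping = c("sex", "age_group")) {
  d <- panel[panel$variable == variable, , drop = FALSE]
  if (!nrow(d)) stopf("variable '%s' absent from panel", variable)
  missing_cols <- setdiff(grouping, names(d))
  if (length(missing_cols))
    stopf("grouping field(s) absent from panel: %s", paste(missing_cols, collapse = ", "))
  gkey <- if (length(grouping)) {
    interaction(d[grouping], drop = TRUE, sep = ".", lex.order = TRUE)
  } else factor(rep("all", nrow(d)))
  groups <- list()
  mat <- matrix(NA_real_, 12L, nlevels(gkey),
                dimnames = list(NULL, levels(gkey)))
  for (g in levels(gkey)) {
    dg <- d[gkey == g, , drop = FALSE]
    vals <- rep(NA_real_, 12L); n <- integer(12L)
    mu <- tapply(dg$value, factor(dg$month, levels = 1:12), mean)
    cnt <- tapply(dg$value, factor(dg$month, levels = 1:12), length)
    vals[] <- as.numeric(mu)
    n[] <- ifelse(is.na(cnt), 0L, as.integer(cnt))
    groups[[g]] <- monthly_series(vals, label = paste(variable, g, sep = ":"),
                                  units = if (variable == "weight") "kg" else "ng/g",
                                  n_contributing = n)
    mat[, g] <- vals
  }
  pooled_vals <- rowMeans(mat, na.rm = TRUE)
  pooled_n <- as.integer(rowSums(!is.na(mat)))
  pooled_vals[pooled_n == 0L] <- NA_real_
  list(
    groups = groups,
    pooled = monthly_series(pooled_vals,
                            label = paste0(variable, ":pooled"),
                            units = if (variable == "weight") "kg" else "ng/g",
                            n_contributing = pooled_n)
  )
}

#' Monthly profile of demographic events
#'
#' Averages a multi-year event stream into mean events per calendar month:
#' `per_month_mean[m] = (# events in month m across all years) /
#' years_covered`. The max/min-month ratio and the peak and trough months
#' summarize the strength and phase of demographic seasonality.
#'
#' @param events event data.frame (`type`, `year`, `month`).
#' @param event_type `"birth"` or `"death"`.
#' @param years_covered number of years the stream spans; defaults to
#'   `max(year) - min(year) + 1` over all events (so years with zero events
#'   inside the span still count).
#' @return An object of class `demographic_series`: `per_month_mean` (a
#'   [monthly_series()]; `n_contributing` = raw counts), `total_events`,
#'   `years_covered`, `max_min_ratio`, `peak_month`, `trough_month`. With
#'   zero events of the requested type the series is all zeros and the ratio
#'   and months are `NA`.
#' @export
monthly_event_profile <- function(events, event_type, years_covered = NULL) {
  if (is.null(years_covered)) {
    if (!nrow(events)) stopf("cannot infer years_covered from an empty event table")
    years_covered <- max(events$year) - min(events$year) + 1L
  }
  if (!is_count(years_covered, 1)) stopf("years_covered must be an integer >= 1")
  ev <- events[events$type == event_type, , drop = FALSE]
  counts <- integer(12L)
  if (nrow(ev)) {
    tb <- table(factor(ev$month, levels = 1:12))
    counts <- as.integer(tb)
  }
  pm <- counts / years_covered
  if (sum(counts) == 0L) {
    ratio <- NA_real_; peak <- NA_integer_; trough <- NA_integer_
  } else {
    peak <- which.max(pm); trough <- which.min(pm)
    ratio <- if (pm[trough] > 0) pm[peak] / pm[trough] else NA_real_
  }
  structure(list(
    event_type = event_type,
    per_month_mean = monthly_series(pm, label = paste0(event_type, "s/month"),
                                    units = "events/year",
                                    n_contributing = counts),
    total_events = sum(counts),
    years_covered = as.integer(years_covered),
    max_min_ratio = ratio,
    peak_month = peak,
    trough_month = trough
  ), class = "demographic_series")
}

#' @export
print.demographic_series <- function(x, ...) {
  cat(sprintf("Monthly %s profile: %d events over %d years\n",
              x$event_type, x$total_events, x$years_covered))
  print(x$per_month_mean)
  if (!is.na(x$max_min_ratio))
    cat(sprintf("peak %s / trough %s, max/min ratio %.2f\n",
                MONTH_ABB[x$peak_month], MONTH_ABB[x$trough_month], x$max_min_ratio))
  invisible(x)
}
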