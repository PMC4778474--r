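#' Calendar-month series
#'
#' A `monthly_series` holds one value per calendar month (January = 1 ...
#' December = 12). Slots may be missing (`NA`); `n_contributing` records how
#' many raw observations entered each slot (0 for missing slots). This is the
#' universal unit consumed by [lagged_xcorr()]: monthly climatologies, sex-age
#' balanced monthly means of a physiological marker, and mean births or deaths
#' per calendar month are all represented this way.
#'
#' @param values numeric vector of length 12, indexed by calendar month;
#'   `NA` marks months with no data.
#' @param label short name for the series (used in printing and reports).
#' @param units measurement units, e.g. `"ng/g"`, `"kg"`, `"mm"`.
#' @param n_contributing integer vector of length 12: number of observations
#'   behind each slot. Defaults to 1 where `values` is non-missing, 0 where
#'   missing.
#' @return An object of class `monthly_series`.
#' @examples
#' s <- monthly_series(cos(2 * pi * (1:12 - 6) / 12), label = "gcm", units = "ng/g")
#' s
#' zscore(s)
#' @export
monthly_series <- function(values, label = "", units = "", n_contributing = NULL) {
  if (length(values) != 12L)
    stopf("a monthly series needs exactly 12 slots, got %d", length(values))
  values <- as.numeric(values)
  if (any(is.infinite(values))) stopf("monthly series values must be finite or NA")
  if (is.null(n_contributing)) n_contributing <- ifelse(is.na(values), 0L, 1L)
  if (length(n_contributing) != 12L)
    stopf("n_contributing needs exactly 12 slots")
  n_contributing <- as.integer(n_contributing)
  if (any(is.na(values) & n_contributing != 0L))
    stopf("missing slots must have n_contributing = 0")
  structure(
    list(label = as.character(label)[1L], units = as.character(units)[1L],
         values = values, n_contributing = n_contributing),
    class = "monthly_series"
  )
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("Monthly series '%s'%s\n", x$label,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  m <- rbind(value = signif(x$values, 4), n = x$n_contributing)
  colnames(m) <- MONTH_ABB
  print(m)
  invisible(x)
}

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  data.frame(month = 1:12, value = x$values, n = x$n_contributing)
}

#' Read or write a monthly series as CSV
#'
#' The on-disk schema is `month,value,n` with months 1..12; missing slots are
#' empty `value` cells with `n = 0`.
#'
#' @param x a [monthly_series()].
#' @param path file path.
#' @param label,units metadata attached on read (the CSV stores numbers only).
#' @return `write_monthly_series()` returns `path` invisibly;
#'   `read_monthly_series()` returns a `monthly_series`.
#' @export
write_monthly_series <- function(x, path) {
  stopifnot(inherits(x, "monthly_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_monthly_series
#' @export
read_monthly_series <- function(path, label = "", units = "") {
  d <- utils::read.csv(path)
  if (!all(c("month", "value") %in% names(d)))
    stopf("%s: expected columns month,value[,n]", path)
  vals <- rep(NA_real_, 12); n <- integer(12)
  vals[d$month] <- d$value
  n[d$month] <- if ("n" %in% names(d)) d$n else ifelse(is.na(d$value), 0L, 1L)
  monthly_series(vals, label = label, units = units, n_contributing = n)
}

#' Standardize a monthly series to Z-scores
#'
#' Non-missing slots are transformed to `(x - mean) / sd` where the mean and
#' sample standard deviation (denominator `n - 1`) are taken over the
#' non-missing slots; missing slots stay missing. Z-scoring lets series in
#' different units (hormone concentrations, kilograms, millimetres of rain)
#' be overlaid on one axis; it does not change Spearman correlations.
#'
#' @param x a [monthly_series()] with at least 2 non-missing slots and
#'   nonzero variance.
#' @return a `monthly_series` with mean 0 and SD 1 over its non-missing slots.
#' @export
zscore <- function(x) {
  stopifnot(inherits(x, "monthly_series"))
  ok <- !is.na(x$values)
  if (sum(ok) < 2L) stopf("zscore needs at least 2 non-missing months")
  mu <- mean(x$values[ok]); s <- stats::sd(x$values[ok])
  if (!is.finite(s) || s == 0) stopf("zscore: series has zero variance")
  out <- x
  out$values[ok] <- (x$values[ok] - mu) / s
  out$units <- "z"
  out
}

#' Percent difference between two months of a series
#'
#' Computes `100 * (value[month_a] - value[month_b]) / value[month_b]`, the
#' form in which seasonal contrasts are usually quoted (e.g. "x% higher in the
#' wettest month than in the driest month").
#'
#' @param x a [monthly_series()].
#' @param month_a,month_b calendar months 1..12; `month_b` is the reference.
#' @return percent difference (a bare number, already scaled by 100).
#' @export
pct_diff <- function(x, month_a, month_b) {
  stopifnot(inherits(x, "monthly_series"))
  if (!is_count(month_a, 1) || month_a > 12 || !is_count(month_b, 1) || month_b > 12)
    stopf("months must be integers in 1..12")
  a <- x$values[month_a]; b <- x$values[month_b]
  if (is.na(a) || is.na(b)) stopf("pct_diff: month %d or %d is missing", month_a, month_b)
  if (b == 0) stopf("pct_diff: reference month %d has value 0", month_b)
  100 * (a - b) / b
}

#' Rotate a 12-month vector forward
#'
#' `rotate_months(v, k)[m]` equals `v[m - k]` with circular wrapping, i.e. the
#' rotated series lags the original by `k` months (its January value is the
#' original's value from `k` months earlier).
#'
#' @param v numeric vector of length 12.
#' @param k integer shift in months (may be negative).
#' @return the rotated vector.
#' @export
rotate_months <- function(v, k) {
  stopifnot(length(v) == 12L)
  v[wrap_month(1:12 - as.integer(k))]
}

#' Climate as a pair of monthly series
#'
#' @param rainfall [monthly_series()] of total monthly rainfall in mm, all 12
#'   months present and nonnegative.
#' @param temperature [monthly_series()] of mean monthly temperature in
#'   degrees Celsius, all 12 months present.
#' @return An object of class `climate_series`.
#' @export
climate_series <- function(rainfall, temperature) {
  stopifnot(inherits(rainfall, "monthly_series"), inherits(temperature, "monthly_series"))
  if (anyNA(rainfall$values) || anyNA(temperature$values))
    stopf("climate series must have all 12 months present")
  if (any(rainfall$values < 0)) stopf("rainfall must be nonnegative")
  structure(list(rainfall = rainfall, temperature = temperature),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  print(x$rainfall); print(x$temperature); invisible(x)
}

#' Read or write climate as CSV
#'
#' Schema: `month,rainfall_mm,temperature_c`, months 1..12.
#'
#' @param x a [climate_series()].
#' @param path file path.
#' @return `read_climate()` returns a `climate_series`.
#' @export
write_climate <- function(x, path) {
  stopifnot(inherits(x, "climate_series"))
  d <- data.frame(month = 1:12, rainfall_mm = x$rainfall$values,
                  temperature_c = x$temperature$values)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_climate
#' @export
read_climate <- function(path) {
  d <- utils::read.csv(path)
  need <- c("month", "rainfall_mm", "temperature_c")
  if (!all(need %in% names(d))) stopf("%s: expected columns %s", path, paste(need, collapse = ","))
  d <- d[order(d$month), ]
  climate_series(
    monthly_series(d$rainfall_mm, label = "rainfall", units = "mm"),
    monthly_series(d$temperature_c, label = "temperature", units = "degC")
  )
}
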