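#' Allowed lag sets for a cross-correlation pair
#'
#' A `lag_spec` encodes which integer month lags a variable pair is allowed
#' to take, together with the alignment rule for shifting 12-slot calendar
#' series. The sign convention is fixed throughout the package:
#' **lag k > 0 means the second series follows the first by k months**
#' (the first series leads).
#'
#' `build_lag_spec()` constructs the spec for the standard pair types, which
#' encode directionality assumptions about cause preceding effect:
#' \describe{
#'   \item{`marker_vs_deaths`}{lags `0..K`: deaths may follow a physiological
#'     marker but never precede it.}
#'   \item{`climate_vs_marker`}{lags `0..K`: the marker may follow climate,
#'     never the reverse.}
#'   \item{`marker_vs_births`}{lags `-K..K`: a birth month also stands for a
#'     conception 22 months earlier (= 2 months later in calendar phase), so
#'     no direction can be assumed a priori.}
#'   \item{`marker_vs_marker`}{lags `-K..K`: no a priori ordering between two
#'     markers.}
#' }
#'
#' @param allowed_lags integer vector of permitted lags (nonempty, within
#'   `[-max_abs_lag, max_abs_lag]`).
#' @param max_abs_lag largest admissible absolute lag in months (default 3).
#' @param alignment `"circular"` treats the 12 calendar slots as a cycle
#'   (December adjacent to January — appropriate for climatologies and
#'   multi-year monthly averages); `"truncated"` drops months shifted out of
#'   the 1..12 range.
#' @param direction_label free-text note on the directionality assumption.
#' @param pair_type one of `"marker_vs_deaths"`, `"marker_vs_births"`,
#'   `"climate_vs_marker"`, `"marker_vs_marker"`.
#' @return An object of class `lag_spec`.
#' @examples
#' build_lag_spec("marker_vs_deaths", max_abs_lag = 3)$allowed_lags  # 0 1 2 3
#' build_lag_spec("marker_vs_births", max_abs_lag = 2)$allowed_lags  # -2..2
#' @export
lag_spec <- function(allowed_lags, max_abs_lag = max(abs(allowed_lags)),
                     alignment = c("circular", "truncated"),
                     direction_label = "") {
  alignment <- match.arg(alignment)
  allowed_lags <- sort(unique(as.integer(allowed_lags)))
  if (length(allowed_lags) == 0L) stopf("allowed_lags must be nonempty")
  if (!is_count(max_abs_lag)) stopf("max_abs_lag must be a nonnegative integer")
  if (any(abs(allowed_lags) > max_abs_lag))
    stopf("allowed_lags must lie within [-%d, %d]", max_abs_lag, max_abs_lag)
  structure(list(allowed_lags = allowed_lags, max_abs_lag = as.integer(max_abs_lag),
                 alignment = alignment, direction_label = direction_label),
            class = "lag_spec")
}

#' @rdname lag_spec
#' @export
build_lag_spec <- function(pair_type, max_abs_lag = 3,
                           alignment = c("circular", "truncated")) {
  alignment <- match.arg(alignment)
  if (!is_count(max_abs_lag)) stopf("max_abs_lag must be a nonnegative integer")
  K <- as.integer(max_abs_lag)
  lags <- switch(pair_type,
    marker_vs_deaths  = 0:K,
    climate_vs_marker = 0:K,
    marker_vs_births  = -K:K,
    marker_vs_marker  = -K:K,
    stopf("unknown pair_type '%s'", pair_type)
  )
  label <- switch(pair_type,
    marker_vs_deaths  = "deaths may follow the marker, never precede it",
    climate_vs_marker = "the marker may follow climate, never precede it",
    marker_vs_births  = "births may lead or follow (birth month also stands for conception)",
    marker_vs_marker  = "no a priori ordering"
  )
  lag_spec(lags, K, alignment, label)
}

#' @export
print.lag_spec <- function(x, ...) {
  cat(sprintf("Lag spec: lags {%s}, %s alignment\n",
              paste(x$allowed_lags, collapse = ", "), x$alignment))
  if (nzchar(x$direction_label)) cat("  ", x$direction_label, "\n", sep = "")
  invisible(x)
}
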