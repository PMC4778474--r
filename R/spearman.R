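#' Spearman rank correlation (midranks for ties)
#'
#' Spearman's rho is the Pearson correlation of the two rank vectors, with
#' tied values receiving their average (mid) rank. It is invariant to any
#' strictly monotone transform of either input, which makes it the right
#' correlation for short, non-normal monthly series. Positions missing in
#' either vector are dropped pairwise before ranking.
#'
#' This is computed from first principles (midranks plus the explicit
#' product-moment formula) rather than delegated, because the lagged
#' cross-correlation machinery reuses the rank decomposition internally.
#'
#' @param x,y numeric vectors of equal length; `NA` allowed.
#' @return Spearman's rho, a number in `[-1, 1]`.
#' @examples
#' spearman_rho(c(3, 1, 2), c(3, 1, 2))   # 1
#' spearman_rho(1:4, c(4, 3, 2, 1))       # -1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("spearman_rho needs at least 3 complete pairs, got %d", n)
  rx <- midrank(x); ry <- midrank(y)
  vx <- sum((rx - mean(rx))^2); vy <- sum((ry - mean(ry))^2)
  if (vx == 0 || vy == 0) stopf("spearman_rho: constant input (zero rank variance)")
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(vx * vy)
  # clip float fuzz at the boundary
  max(-1, min(1, r))
}

# average ranks with midranks for ties; no NA handling (caller filters)
midrank <- function(x) {
  o <- order(x)
  n <- length(x)
  r <- numeric(n)
  sx <- x[o]
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && sx[j + 1L] == sx[i]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

# crude large-sample p for Spearman's rho via the t approximation;
# reported alongside permutation p's for comparison only (n = 12 is short)
spearman_p_asymptotic <- function(rho, n) {
  if (is.na(rho) || n < 4L) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}
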