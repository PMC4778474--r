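# internal helpers shared across modules

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded package functions do not perturb user sessions.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

MONTH_ABB <- month.abb

# calendar-month arithmetic on 1..12 (wraps; shift may be negative)
wrap_month <- function(m) ((m - 1L) %% 12L) + 1L
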