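#' Generate a monsoon climate climatology
#'
#' Produces one rainfall and one temperature value per calendar month.
#' Rainfall follows a unimodal monsoon profile,
#' `min + (max - min) * ((1 + cos(2*pi*(m - peak)/12)) / 2)^shape`, peaking in
#' the wet season (August by default) and falling to `rainfall_min` in the
#' opposite dry month; temperature is a cosine peaking just before monsoon
#' onset (May by default). Both are deterministic functions of the
#' configuration: a climatology averages out year-to-year weather, so no
#' noise is added.
#'
#' @param config a [synth_config()].
#' @return a [climate_series()].
#' @export
gen_climate <- function(config) {
  config <- validate_synth_config(config)
  m <- 1:12
  rain <- config$rainfall_min + (config$rainfall_max - config$rainfall_min) *
    ((1 + cos(2 * pi * (m - config$rainfall_peak_month) / 12)) / 2)^config$rainfall_shape
  temp <- config$temperature_mean + config$temperature_amplitude *
    cos(2 * pi * (m - config$temperature_peak_month) / 12)
  climate_series(
    monthly_series(rain, label = "rainfall", units = "mm"),
    monthly_series(temp, label = "temperature", units = "degC")
  )
}

AGE_GROUPS <- c("0-16", "17-44", "45+")

age_group_of <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 16, 44, Inf), labels = AGE_GROUPS)
}

#' Generate a study population roster
#'
#' Draws `n_individuals` core animals (sampled monthly for GCM, and for
#' weight if adult) and `n_weight_only_adults` supplementary adults measured
#' for weight only, mirroring a design in which hormone sampling happens at
#' one main camp and weighing is extended to auxiliary camps. Sex is Bernoulli
#' with `prop_female`; age class follows `age_group_weights` with ages drawn
#' uniformly inside each class (4-16 / 17-44 / 45-69 years).
#'
#' @param config a [synth_config()].
#' @return a data.frame with columns `id`, `sex` (`"female"`/`"male"`),
#'   `age_years`, `age_group` (`"0-16"`/`"17-44"`/`"45+"`), `camp`,
#'   `gcm_sampled` (logical).
#' @export
gen_population <- function(config) {
  config <- validate_synth_config(config)
  with_seed(config$seed + 1L, {
    n <- config$n_individuals
    grp <- sample(1:3, n, replace = TRUE, prob = config$age_group_weights)
    lo <- c(4, 17, 45)[grp]; hi <- c(16, 44, 69)[grp]
    core <- data.frame(
      sex = ifelse(stats::runif(n) < config$prop_female, "female", "male"),
      age_years = floor(stats::runif(n, lo, hi + 1)),
      camp = "Pyinmana",
      gcm_sampled = TRUE,
      stringsAsFactors = FALSE
    )
    ne <- config$n_weight_only_adults
    extra <- if (ne > 0) {
      wa <- config$age_group_weights[2:3]
      ga <- sample(2:3, ne, replace = TRUE, prob = wa / sum(wa))
      data.frame(
        sex = ifelse(stats::runif(ne) < config$prop_female, "female", "male"),
        age_years = floor(stats::runif(ne, c(17, 45)[ga - 1], c(44, 69)[ga - 1] + 1)),
        camp = sample(c("Kawlin", "EastKatha", "WestKatha"), ne, replace = TRUE,
                      prob = c(24, 15, 12)),
        gcm_sampled = FALSE,
        stringsAsFactors = FALSE
      )
    } else core[0, ]
    pop <- rbind(core, extra)
    pop$id <- sprintf("E%03d", seq_len(nrow(pop)))
    pop$age_group <- as.character(age_group_of(pop$age_years))
    pop[, c("id", "sex", "age_years", "age_group", "camp", "gcm_sampled")]
  })
}

# AR(1) residual matrix, months x individuals, stationary initialization
ar1_matrix <- function(n_months, n_ind, phi, sigma) {
  if (sigma == 0) return(matrix(0, n_months, n_ind))
  E <- matrix(0, n_months, n_ind)
  E[1L, ] <- stats::rnorm(n_ind, 0, sigma / sqrt(1 - phi^2))
  if (n_months > 1L) {
    Z <- matrix(stats::rnorm((n_months - 1L) * n_ind, 0, sigma), n_months - 1L, n_ind)
    for (t in 2:n_months) E[t, ] <- phi * E[t - 1L, ] + Z[t - 1L, ]
  }
  E
}

#' Generate a longitudinal physiology panel
#'
#' For each individual and variable, the value in calendar month `m` is
#' `baseline(sex, age group) + b_i + A * cos(2*pi*(m - peak)/12) + e_m`,
#' where `b_i ~ Normal(0, sigma_individual^2)` is the individual's random
#' intercept and `e` is a stationary AR(1) process with coefficient
#' `ar1_phi` and innovation SD `sigma_noise`. GCM rows are produced for the
#' core (gcm-sampled) individuals; weight rows only for adults (ages 17+),
#' and weight is deleted in the configured missing months. GCM values are
#' floored at 0 (with default settings the floor is hit for well under 0.1%
#' of observations).
#'
#' @param population roster from [gen_population()].
#' @param climate a [climate_series()]; accepted for interface completeness
#'   and validated, but the seasonal signal is parameterized directly by the
#'   cosine terms of the configuration rather than driven through climate.
#' @param config a [synth_config()].
#' @return a longitudinal panel data.frame with columns `id`, `sex`,
#'   `age_years`, `age_group`, `camp`, `month`, `variable`
#'   (`"gcm"`/`"weight"`), `value`. For weight rows `age_group` is one of the
#'   two adult classes.
#' @export
gen_panel <- function(population, climate, config) {
  config <- validate_synth_config(config)
  if (!nrow(population)) stopf("population must be non-empty")
  stopifnot(inherits(climate, "climate_series"))
  with_seed(config$seed + 2L, {
    m <- 1:12
    panels <- list()

    gcm_pop <- population[population$gcm_sampled, , drop = FALSE]
    if (nrow(gcm_pop)) {
      n <- nrow(gcm_pop)
      season <- config$seasonal_amplitude_gcm *
        cos(2 * pi * (m - config$seasonal_peak_month_gcm) / 12)
      b <- stats::rnorm(n, 0, config$sigma_individual_gcm)
      E <- ar1_matrix(12L, n, config$ar1_phi, config$sigma_noise_gcm)
      V <- config$gcm_baseline + season +
        matrix(b, 12L, n, byrow = TRUE) + E
      V <- pmax(V, 0)
      panels$gcm <- data.frame(
        id = rep(gcm_pop$id, each = 12L),
        sex = rep(gcm_pop$sex, each = 12L),
        age_years = rep(gcm_pop$age_years, each = 12L),
        age_group = rep(gcm_pop$age_group, each = 12L),
        camp = rep(gcm_pop$camp, each = 12L),
        month = rep(m, nrow(gcm_pop)),
        variable = "gcm",
        value = as.vector(V),
        stringsAsFactors = FALSE
      )
    }

    wt_pop <- population[population$age_group != "0-16", , drop = FALSE]
    if (nrow(wt_pop)) {
      n <- nrow(wt_pop)
      base <- config$weight_baseline *
        ifelse(wt_pop$sex == "male", config$weight_male_multiplier, 1) *
        ifelse(wt_pop$age_group == "45+", config$weight_old_multiplier, 1)
      season <- config$seasonal_amplitude_weight *
        cos(2 * pi * (m - config$seasonal_peak_month_weight) / 12)
      b <- stats::rnorm(n, 0, config$sigma_individual_weight)
      E <- ar1_matrix(12L, n, config$ar1_phi, config$sigma_noise_weight)
      V <- matrix(base + b, 12L, n, byrow = TRUE) + season + E
      wt <- data.frame(
        id = rep(wt_pop$id, each = 12L),
        sex = rep(wt_pop$sex, each = 12L),
        age_years = rep(wt_pop$age_years, each = 12L),
        age_group = rep(wt_pop$age_group, each = 12L),
        camp = rep(wt_pop$camp, each = 12L),
        month = rep(m, nrow(wt_pop)),
        variable = "weight",
        value = as.vector(V),
        stringsAsFactors = FALSE
      )
      wt <- wt[!(wt$month %in% config$missing_months_weight), , drop = FALSE]
      panels$weight <- wt
    }

    out <- do.call(rbind, panels)
    rownames(out) <- NULL
    out
  })
}

#' Generate a multi-decade demographic event stream
#'
#' Monthly birth and death counts are drawn independently as
#' `Poisson(intensity[month])` for each of `years_demography` years, then
#' expanded to one row per event. Individual life histories are not
#' simulated: the downstream analysis consumes only monthly counts.
#'
#' @param config a [synth_config()].
#' @return a data.frame with columns `type` (`"birth"`/`"death"`), `year`
#'   (1..years), `month` (1..12), one row per event.
#' @export
gen_demography <- function(config) {
  config <- validate_synth_config(config)
  with_seed(config$seed + 3L, {
    yrs <- config$years_demography
    grid <- expand.grid(year = seq_len(yrs), month = 1:12)
    grid <- grid[order(grid$year, grid$month), ]
    out <- list()
    for (ty in c("birth", "death")) {
      lam <- config[[paste0(ty, "_intensity_by_month")]]
      counts <- stats::rpois(nrow(grid), lam[grid$month])
      out[[ty]] <- data.frame(
        type = rep(ty, sum(counts)),
        year = rep(grid$year, counts),
        month = rep(grid$month, counts),
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Conception month implied by a birth month
#'
#' Maps a calendar birth month to the calendar month of conception
#' `gestation_months` earlier (wrapping the calendar). With the 22-month
#' elephant gestation, a January birth implies a March conception two
#' calendar-phase months later, which is why a +2 lag against a birth series
#' can stand for a lag-0 association with conception timing.
#'
#' @param month calendar month(s) 1..12.
#' @param gestation_months gestation length in months (default 22).
#' @return calendar month(s) of conception.
#' @examples
#' conception_month(1)  # 3
#' @export
conception_month <- function(month, gestation_months = 22) {
  if (any(month < 1 | month > 12 | month != round(month)))
    stopf("month must be in 1..12")
  wrap_month(as.integer(month) - as.integer(gestation_months))
}

#' Read or write panels and event tables as CSV
#'
#' Panel schema: `id,sex,age_years,age_group,camp,month,variable,value`.
#' Event schema: `type,year,month`.
#'
#' @param x a panel or event data.frame.
#' @param path file path.
#' @return readers return the validated data.frame.
#' @export
write_panel <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age_group", "month", "variable", "value")
  if (!all(need %in% names(d)))
    stopf("%s: panel needs columns %s", path, paste(need, collapse = ","))
  validate_panel(d)
}

#' @rdname write_panel
#' @export
write_events <- function(x, path) {
  utils::write.csv(x[, c("type", "year", "month")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "year", "month")
  if (!all(need %in% names(d)))
    stopf("%s: event table needs columns %s", path, paste(need, collapse = ","))
  if (nrow(d) && any(d$month < 1 | d$month > 12)) stopf("event months must be in 1..12")
  d
}

validate_panel <- function(d) {
  if (any(d$month < 1 | d$month > 12 | d$month != round(d$month)))
    stopf("panel months must be integers in 1..12")
  if (any(!is.finite(d$value))) stopf("panel values must be finite")
  if (any(d$value[d$variable == "gcm"] < 0)) stopf("GCM values must be >= 0")
  if (any(d$value[d$variable == "weight"] <= 0)) stopf("weight values must be > 0")
  key <- paste(d$id, d$month, d$variable)
  if (anyDuplicated(key))
    stopf("panel has duplicate (id, month, variable) observations")
  d
}
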