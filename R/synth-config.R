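#' Configuration for the synthetic study-system generator
#'
#' `synth_config()` collects every parameter of the synthetic data generator
#' in one validated object. The defaults emulate the study system the
#' analysis is designed for: a semi-captive working Asian elephant population
#' under a tropical monsoon climate, with 75 core individuals sampled monthly
#' for faecal glucocorticoid metabolites (GCM) plus 51 supplementary
#' weight-only adults (116 weighed animals in total), weight unmeasured in
#' August and November, multi-decade monthly birth and death streams with
#' births peaking in the cool dry season (January, max/min ratio ~1.8) and
#' deaths peaking in the cool dry extremes (January vs November, ratio ~2.0).
#'
#' Seasonal signals are single-harmonic cosines
#' `A * cos(2*pi*(m - peak)/12)`; residual noise is AR(1) with innovation SD
#' `sigma_noise_*` (stationary SD `sigma_noise/sqrt(1 - ar1_phi^2)`); each
#' individual carries a Normal random intercept per variable. Weight
#' baselines are multiplicative by sex and age: adult males default to 1.259x
#' the adult-female baseline and the oldest age class to 1.075x its
#' adult counterpart.
#'
#' @param n_individuals core individuals sampled for GCM (and, if adult, for
#'   weight). Default 75.
#' @param prop_female probability an individual is female. Default 43/75.
#' @param age_group_weights probabilities of the three age classes
#'   `0-16` / `17-44` / `45+` years; must sum to 1. Default `c(.15,.55,.30)`.
#' @param n_weight_only_adults supplementary adults measured for weight only,
#'   spread over the auxiliary camps. Default 51.
#' @param years_demography years of demographic records generated. Default 57.
#' @param gcm_baseline mean GCM in ng/g dry faeces. Default 55.
#' @param weight_baseline adult-female body weight baseline, kg. Default 2500.
#' @param weight_male_multiplier,weight_old_multiplier multiplicative sex and
#'   old-age effects on the weight baseline. Defaults 1.259 and 1.075.
#' @param seasonal_amplitude_gcm,seasonal_amplitude_weight cosine amplitudes
#'   (ng/g; kg). Defaults 15 and 50.
#' @param seasonal_peak_month_gcm,seasonal_peak_month_weight calendar month of
#'   each cosine peak. Defaults 7 (July, the middle of the June-August
#'   elevated-GCM period, roughly in phase with monsoon rain) and 9
#'   (September) — one month after
#'   the default rainfall peak, encoding a 1-month climate-to-weight lead.
#' @param sigma_individual_gcm,sigma_individual_weight SD of the individual
#'   random intercepts (ng/g; kg). Defaults 12 and 150.
#' @param ar1_phi AR(1) coefficient of the month-to-month residual process,
#'   `|phi| < 1`. Default 0.3.
#' @param sigma_noise_gcm,sigma_noise_weight AR(1) innovation SDs (ng/g; kg).
#'   Defaults 8 and 35.
#' @param missing_months_weight calendar months with no weight measurements.
#'   Default `c(8, 11)` (August, November).
#' @param birth_intensity_by_month,death_intensity_by_month 12 nonnegative
#'   Poisson rates (expected events per calendar month per year). Defaults
#'   peak in January with max/min ratios 1.8 (births, trough July) and 2.0
#'   (deaths, trough November).
#' @param gestation_months gestation length used by the conception-month
#'   helper. Default 22.
#' @param rainfall_min,rainfall_max,rainfall_peak_month,rainfall_shape shape
#'   of the rainfall climatology: `min + (max - min) *
#'   ((1 + cos(2*pi*(m - peak)/12))/2)^shape`, a unimodal monsoon profile
#'   (peak August by default, dry-season zero opposite the peak). The
#'   exponent sharpens the wet season.
#' @param temperature_mean,temperature_amplitude,temperature_peak_month
#'   cosine temperature climatology in degrees Celsius (default 25 +/- 5,
#'   peaking in May, just before monsoon onset).
#' @param seed integer RNG seed; every generator is deterministic given the
#'   config.
#' @return An object of class `synth_config` (a validated named list).
#' @seealso [gen_climate()], [gen_population()], [gen_panel()],
#'   [gen_demography()], [read_synth_config()]
#' @export
synth_config <- function(
  n_individuals = 75,
  prop_female = 43 / 75,
  age_group_weights = c(0.15, 0.55, 0.30),
  n_weight_only_adults = 51,
  years_demography = 57,
  gcm_baseline = 55,
  weight_baseline = 2500,
  weight_male_multiplier = 1.259,
  weight_old_multiplier = 1.075,
  seasonal_amplitude_gcm = 15,
  seasonal_amplitude_weight = 50,
  seasonal_peak_month_gcm = 7,
  seasonal_peak_month_weight = 9,
  sigma_individual_gcm = 12,
  sigma_individual_weight = 150,
  ar1_phi = 0.3,
  sigma_noise_gcm = 8,
  sigma_noise_weight = 35,
  missing_months_weight = c(8, 11),
  birth_intensity_by_month = c(4.4, 4.3, 4.1, 3.8, 3.4, 2.8, 2.45,
                               2.6, 3.0, 3.4, 3.8, 4.2),
  death_intensity_by_month = c(2.0, 1.9, 1.8, 1.7, 1.6, 1.5, 1.45,
                               1.35, 1.25, 1.1, 1.0, 1.8),
  gestation_months = 22,
  rainfall_min = 0,
  rainfall_max = 320,
  rainfall_peak_month = 8,
  rainfall_shape = 1.5,
  temperature_mean = 25,
  temperature_amplitude = 5,
  temperature_peak_month = 5,
  seed = 1
) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (!is_count(cfg$n_individuals, 1)) stopf("n_individuals must be an integer >= 1")
  if (!is_count(cfg$n_weight_only_adults, 0)) stopf("n_weight_only_adults must be >= 0")
  if (!is_count(cfg$years_demography, 1)) stopf("years_demography must be >= 1")
  if (!is_count(cfg$gestation_months, 1)) stopf("gestation_months must be >= 1")
  if (!is_count(cfg$seed)) stopf("seed must be a nonnegative integer")
  if (cfg$prop_female < 0 || cfg$prop_female > 1) stopf("prop_female must lie in [0, 1]")
  w <- cfg$age_group_weights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stopf("age_group_weights must be 3 nonnegative fractions summing to 1")
  if (abs(cfg$ar1_phi) >= 1) stopf("ar1_phi must satisfy |phi| < 1")
  sds <- c(cfg$sigma_individual_gcm, cfg$sigma_individual_weight,
           cfg$sigma_noise_gcm, cfg$sigma_noise_weight,
           cfg$seasonal_amplitude_gcm, cfg$seasonal_amplitude_weight)
  if (any(sds < 0)) stopf("SDs and amplitudes must be >= 0")
  for (f in c("seasonal_peak_month_gcm", "seasonal_peak_month_weight",
              "rainfall_peak_month", "temperature_peak_month")) {
    if (cfg[[f]] < 1 || cfg[[f]] > 12) stopf("%s must lie in 1..12", f)
  }
  mm <- cfg$missing_months_weight
  if (length(mm) && (any(mm != round(mm)) || any(mm < 1) || any(mm > 12)))
    stopf("missing_months_weight must be calendar months in 1..12")
  for (f in c("birth_intensity_by_month", "death_intensity_by_month")) {
    v <- cfg[[f]]
    if (length(v) != 12L || any(!is.finite(v)) || any(v < 0))
      stopf("%s must be 12 nonnegative rates", f)
  }
  if (cfg$rainfall_min < 0 || cfg$rainfall_max < cfg$rainfall_min)
    stopf("rainfall range must satisfy 0 <= min <= max")
  if (cfg$rainfall_shape <= 0) stopf("rainfall_shape must be positive")
  if (cfg$temperature_amplitude < 0) stopf("temperature_amplitude must be >= 0")
  if (cfg$weight_baseline <= 0 || cfg$gcm_baseline < 0)
    stopf("baselines must be positive")
  if (cfg$weight_male_multiplier <= 0 || cfg$weight_old_multiplier <= 0)
    stopf("weight multipliers must be positive")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study-system configuration\n")
  cat(sprintf("  individuals: %d core (prop female %.2f) + %d weight-only adults\n",
              x$n_individuals, x$prop_female, x$n_weight_only_adults))
  cat(sprintf("  GCM: baseline %.1f ng/g, amplitude %.1f, peak month %d\n",
              x$gcm_baseline, x$seasonal_amplitude_gcm, x$seasonal_peak_month_gcm))
  cat(sprintf("  weight: baseline %.0f kg, amplitude %.0f, peak month %d, missing months {%s}\n",
              x$weight_baseline, x$seasonal_amplitude_weight,
              x$seasonal_peak_month_weight,
              paste(x$missing_months_weight, collapse = ",")))
  cat(sprintf("  noise: AR(1) phi %.2f; innovation SD %.1f (gcm) / %.1f (kg)\n",
              x$ar1_phi, x$sigma_noise_gcm, x$sigma_noise_weight))
  cat(sprintf("  demography: %d years; births %.1f-%.1f, deaths %.1f-%.1f per month\n",
              x$years_demography,
              min(x$birth_intensity_by_month), max(x$birth_intensity_by_month),
              min(x$death_intensity_by_month), max(x$death_intensity_by_month)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read or write a generator configuration
#'
#' Configurations are stored as flat JSON or YAML mapping field names to
#' values (the format is chosen by file extension). Unknown fields raise an
#' error; omitted fields take their [synth_config()] defaults.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @param cfg a `synth_config`.
#' @return `read_synth_config()` returns a validated `synth_config`.
#' @export
read_synth_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stopf("config must be .json, .yaml or .yml, got '%s'", ext)
  )
  known <- names(formals(synth_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(synth_config, vals)
}

#' @rdname read_synth_config
#' @export
write_synth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else stopf("config must be .json, .yaml or .yml")
  invisible(path)
}
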