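test_that("config validation enforces the documented invariants", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(n_individuals = 0), "n_individuals")
  expect_error(synth_config(ar1_phi = 1), "ar1_phi")
  expect_error(synth_config(age_group_weights = c(.5, .5, .5)), "summing to 1")
  expect_error(synth_config(seasonal_peak_month_gcm = 13), "1\\.\\.12")
  expect_error(synth_config(birth_intensity_by_month = rep(-1, 12)), "nonnegative")
  expect_error(synth_config(sigma_noise_gcm = -1), ">= 0")
  expect_error(synth_config(missing_months_weight = c(0, 5)), "1\\.\\.12")
})

test_that("config round-trips through JSON and YAML", {
  cfg <- synth_config(n_individuals = 10, ar1_phi = 0.25, seed = 42)
  for (ext in c("json", "yaml")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_synth_config(cfg, p)
    cfg2 <- read_synth_config(p)
    expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
    unlink(p)
  }
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(list(not_a_field = 1), p, auto_unbox = TRUE)
  expect_error(read_synth_config(p), "unknown config field")
  unlink(p)
})

test_that("climate has a monsoon shape and is deterministic", {
  cfg <- synth_config()
  cl <- gen_climate(cfg)
  rain <- cl$rainfall$values; temp <- cl$temperature$values
  expect_true(which.max(rain) %in% 6:10)       # monsoon peak
  expect_true(which.max(temp) %in% 4:5)        # hot season before monsoon
  expect_lt(rain[1], rain[7])                  # dry January vs wet July
  expect_true(all(rain >= 0))
  expect_identical(gen_climate(cfg), cl)       # same config, same climatology
  # configurable range brackets the documented extremes
  cfg2 <- synth_config(rainfall_max = 906, temperature_amplitude = 10,
                       temperature_mean = 24)
  cl2 <- gen_climate(cfg2)
  expect_equal(max(cl2$rainfall$values), 906)
  expect_gte(min(cl2$temperature$values), 14)
  expect_lte(max(cl2$temperature$values), 34)
  # zero amplitude: flat series
  flat <- gen_climate(synth_config(rainfall_min = 100, rainfall_max = 100,
                                   temperature_amplitude = 0))
  expect_true(all(flat$rainfall$values == 100))
  expect_equal(length(unique(flat$temperature$values)), 1L)
})

test_that("population sampling matches the configured frame", {
  cfg <- synth_config(seed = 3)
  pop <- gen_population(cfg)
  core <- pop[pop$gcm_sampled, ]
  expect_equal(nrow(core), 75L)
  expect_equal(nrow(pop), 75L + 51L)
  # expected 43 females among the 75; allow 4 binomial SDs (~4.3 each way)
  expect_lt(abs(sum(core$sex == "female") - 43), 18)
  # age group labels consistent with ages
  expect_true(all(pop$age_group[pop$age_years <= 16] == "0-16"))
  expect_true(all(pop$age_group[pop$age_years >= 45] == "45+"))
  expect_true(all(pop$age_group[pop$age_years >= 17 & pop$age_years <= 44] == "17-44"))
  # supplementary animals are adults from the auxiliary camps
  extra <- pop[!pop$gcm_sampled, ]
  expect_true(all(extra$age_group != "0-16"))
  expect_true(all(extra$camp %in% c("Kawlin", "EastKatha", "WestKatha")))
  expect_identical(gen_population(cfg), pop)
  expect_true(all(gen_population(synth_config(prop_female = 1))$sex == "female"))
})

test_that("the noise-free panel is exactly the cosine profile", {
  cfg <- noiseless_config(n_individuals = 6, n_weight_only_adults = 2, seed = 9)
  pop <- gen_population(cfg)
  panel <- gen_panel(pop, gen_climate(cfg), cfg)
  g <- panel[panel$variable == "gcm", ]
  expect_equal(g$value,
               cfg$gcm_baseline + cfg$seasonal_amplitude_gcm *
                 cos(2 * pi * (g$month - cfg$seasonal_peak_month_gcm) / 12),
               tolerance = 1e-12)
  w <- panel[panel$variable == "weight", ]
  base <- cfg$weight_baseline *
    ifelse(w$sex == "male", cfg$weight_male_multiplier, 1) *
    ifelse(w$age_group == "45+", cfg$weight_old_multiplier, 1)
  expect_equal(w$value,
               base + cfg$seasonal_amplitude_weight *
                 cos(2 * pi * (w$month - cfg$seasonal_peak_month_weight) / 12),
               tolerance = 1e-12)
})

test_that("panel structure: missing weight months, adults only, determinism", {
  cfg <- synth_config(seed = 17)
  pop <- gen_population(cfg)
  cl <- gen_climate(cfg)
  panel <- gen_panel(pop, cl, cfg)
  w <- panel[panel$variable == "weight", ]
  expect_false(any(w$month %in% c(8, 11)))
  expect_setequal(unique(w$month), setdiff(1:12, c(8, 11)))
  expect_false(any(w$age_group == "0-16"))
  expect_true(all(panel$value[panel$variable == "gcm"] >= 0))
  expect_identical(gen_panel(pop, cl, cfg), panel)
  expect_silent(seasoncorr:::validate_panel(panel))
  expect_error(gen_panel(pop[0, ], cl, cfg), "non-empty")
})

test_that("between-individual variance of means matches theory at phi = 0", {
  # var of per-individual means ~= sigma_ind^2 + sigma_noise^2 / 12
  cfg <- synth_config(n_individuals = 2500, n_weight_only_adults = 0,
                      sigma_individual_gcm = 10, sigma_noise_gcm = 6,
                      ar1_phi = 0, gcm_baseline = 500,
                      seasonal_amplitude_gcm = 0, seed = 23)
  panel <- gen_panel(gen_population(cfg), gen_climate(cfg), cfg)
  g <- panel[panel$variable == "gcm", ]
  v <- var(tapply(g$value, g$id, mean))
  expect_equal(v, 10^2 + 6^2 / 12, tolerance = 0.1)
})

test_that("simulated residuals have the configured lag-1 autocorrelation", {
  cfg <- synth_config(n_individuals = 2500, n_weight_only_adults = 0,
                      sigma_individual_gcm = 0, sigma_noise_gcm = 1,
                      ar1_phi = 0.5, gcm_baseline = 500,
                      seasonal_amplitude_gcm = 0, seed = 29)
  panel <- gen_panel(gen_population(cfg), gen_climate(cfg), cfg)
  g <- panel[panel$variable == "gcm", ]
  E <- matrix(g$value[order(g$id, g$month)] - 500, nrow = 12)
  phi_hat <- sum(E[1:11, ] * E[2:12, ]) / sum(E[1:11, ]^2)
  expect_lt(abs(phi_hat - 0.5), 0.05)
})

test_that("demographic events are Poisson with the configured intensities", {
  cfg0 <- synth_config(birth_intensity_by_month = rep(0, 12),
                       death_intensity_by_month = rep(0, 12))
  expect_equal(nrow(gen_demography(cfg0)), 0L)

  cfg <- synth_config(birth_intensity_by_month = rep(2, 12),
                      years_demography = 50, seed = 31)
  ev <- gen_demography(cfg)
  births <- ev[ev$type == "birth", ]
  mean_monthly <- nrow(births) / (50 * 12)
  se <- sqrt(2 / (50 * 12))
  expect_lt(abs(mean_monthly - 2), 3 * se)
  expect_identical(gen_demography(cfg), ev)

  lam <- c(6, rep(4, 5), 2, rep(4, 5))  # Jan max, Jul min, ratio 3
  cfg2 <- synth_config(birth_intensity_by_month = lam, years_demography = 500,
                       seed = 37)
  b2 <- gen_demography(cfg2)
  b2 <- b2[b2$type == "birth", ]
  counts <- table(factor(b2$month, levels = 1:12))
  expect_lt(abs(counts[1] / counts[7] - 3), 3 * 0.05)
})

test_that("conception month wraps the calendar by the gestation length", {
  expect_equal(conception_month(1), 3L)           # Jan birth, Mar conception
  expect_equal(conception_month(12), 2L)
  expect_equal(conception_month(1:12), ((1:12 + 1) %% 12) + 1)
  expect_equal(conception_month(6, gestation_months = 12), 6L)
  expect_error(conception_month(13), "1\\.\\.12")
})

test_that("panel and event tables round-trip through CSV", {
  cfg <- synth_config(n_individuals = 5, n_weight_only_adults = 2,
                      years_demography = 3, seed = 41)
  pop <- gen_population(cfg)
  panel <- gen_panel(pop, gen_climate(cfg), cfg)
  ev <- gen_demography(cfg)
  pf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write_panel(panel, pf); write_events(ev, ef)
  expect_equal(read_panel(pf)$value, panel$value, tolerance = 1e-9)
  expect_equal(nrow(read_events(ef)), nrow(ev))
  unlink(c(pf, ef))
})
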