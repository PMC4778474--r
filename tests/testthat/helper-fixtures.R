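# small programmatic fixtures shared across test files

# minimal panel frame: one row per (id, month) for one variable
tiny_panel <- function(ids, months, values, variable = "gcm",
                       sex = "female", age_group = "17-44", camp = "camp1") {
  data.frame(id = ids, sex = sex, age_years = 30, age_group = age_group,
             camp = camp, month = months, variable = variable, value = values,
             stringsAsFactors = FALSE)
}

# seeded random longitudinal panel: n_ind individuals, random subsets of months
random_panel <- function(n_ind = 8, variable = "gcm", seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_ind), function(i) {
    months <- sort(sample(1:12, sample(2:12, 1)))
    tiny_panel(sprintf("id%02d", i), months, rnorm(length(months), 50, 10),
               variable = variable,
               sex = sample(c("female", "male"), 1),
               age_group = sample(c("17-44", "45+"), 1))
  })
  do.call(rbind, rows)
}

# a noise-free generator configuration (panel is an exact cosine profile)
noiseless_config <- function(...) {
  synth_config(sigma_individual_gcm = 0, sigma_individual_weight = 0,
               ar1_phi = 0, sigma_noise_gcm = 0, sigma_noise_weight = 0, ...)
}

# 12-slot random series with optional missing months, continuous values
random_series <- function(n_missing = 0) {
  v <- rnorm(12)
  if (n_missing > 0) v[sample(1:12, n_missing)] <- NA
  v
}
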