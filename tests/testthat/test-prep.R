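test_that("within-individual centering subtracts each animal's own mean", {
  p <- tiny_panel("a", 1:3, c(10, 12, 14))
  res <- center_within_individual(p, "gcm")
  expect_equal(res$panel$value, c(-2, 0, 2))
  expect_equal(res$individual_means$mean, 12)
  expect_equal(res$individual_means$n_obs, 3L)
  # negated convention flips the sign only
  expect_equal(center_within_individual(p, "gcm", negate = TRUE)$panel$value,
               c(2, 0, -2))
  expect_error(center_within_individual(p, "weight"), "absent")
})

test_that("singletons are dropped with a warning; centering is idempotent", {
  p <- rbind(tiny_panel("a", 1:3, c(10, 12, 14)),
             tiny_panel("b", 5, 99))
  expect_warning(res <- center_within_individual(p, "gcm"), "b")
  expect_false("b" %in% res$panel$id)
  res2 <- center_within_individual(res$panel, "gcm")
  expect_equal(res2$panel$value, res$panel$value, tolerance = 1e-12)
})

test_that("centred values sum to zero for every individual (random panels)", {
  for (s in 1:5) {
    p <- random_panel(n_ind = 10, seed = s)
    res <- suppressWarnings(center_within_individual(p, "gcm"))
    sums <- tapply(res$panel$value, res$panel$id, sum)
    expect_true(all(abs(sums) < 1e-9))
  }
})

test_that("monthly group means average within groups; pooling is balanced", {
  p <- tiny_panel(c("a", "b", "c"), 1, c(1, 2, 3))
  mm <- monthly_group_means(p, "gcm", grouping = character(0))
  expect_equal(mm$groups[[1]]$values[1], 2)
  expect_equal(mm$groups[[1]]$n_contributing[1], 3L)
  expect_true(all(is.na(mm$groups[[1]]$values[2:12])))

  # two groups of unequal size: pooled value is the unweighted mean of means
  p2 <- rbind(tiny_panel(c("a1", "a2", "a3"), 1, c(9, 10, 11), sex = "female"),
              tiny_panel("b1", 1, 20, sex = "male"))
  mm2 <- monthly_group_means(p2, "gcm", grouping = "sex")
  expect_equal(mm2$pooled$values[1], 15)  # (10 + 20) / 2, not the grand mean 12.5
  expect_equal(mm2$pooled$n_contributing[1], 2L)
  expect_error(monthly_group_means(p2, "gcm", grouping = "nope"), "absent")
})

test_that("pooled series equals the brute-force two-step mean on random fixtures", {
  set.seed(14)
  for (rep in 1:5) {
    p <- random_panel(n_ind = 12, seed = rep + 100)
    p$group <- p$sex
    mm <- monthly_group_means(p, "gcm", grouping = "sex")
    for (m in 1:12) {
      if (is.na(mm$pooled$values[m])) {
        expect_equal(sum(p$month == m), 0)
      } else {
        expect_equal(mm$pooled$values[m], oracle_pooled_mean(p, m), tolerance = 1e-12)
      }
    }
  }
})

test_that("group means of a noise-free generated panel equal the cosine exactly", {
  cfg <- noiseless_config(n_individuals = 10, n_weight_only_adults = 0, seed = 2)
  panel <- gen_panel(gen_population(cfg), gen_climate(cfg), cfg)
  mm <- monthly_group_means(panel, "gcm", grouping = c("sex", "age_group"))
  expected <- cfg$gcm_baseline + cfg$seasonal_amplitude_gcm *
    cos(2 * pi * (1:12 - cfg$seasonal_peak_month_gcm) / 12)
  for (g in names(mm$groups)) {
    obs <- mm$groups[[g]]$values
    expect_equal(obs[!is.na(obs)], expected[!is.na(obs)], tolerance = 1e-12)
  }
  expect_equal(mm$pooled$values, expected, tolerance = 1e-12)
})

test_that("adding a constant shifts means but not centred values or z-scores", {
  p <- random_panel(n_ind = 8, seed = 77)
  p2 <- p; p2$value <- p$value + 100
  mm <- monthly_group_means(p, "gcm")$pooled
  mm2 <- monthly_group_means(p2, "gcm")$pooled
  ok <- !is.na(mm$values)
  expect_equal(mm2$values[ok], mm$values[ok] + 100, tolerance = 1e-12)
  c1 <- suppressWarnings(center_within_individual(p, "gcm"))$panel$value
  c2 <- suppressWarnings(center_within_individual(p2, "gcm"))$panel$value
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_equal(zscore(mm)$values, zscore(mm2)$values, tolerance = 1e-12)
})

test_that("monthly event profiles average counts over years", {
  ev <- data.frame(type = "birth", year = rep(1, 24), month = rep(1:12, each = 2))
  prof <- monthly_event_profile(ev, "birth", years_covered = 1)
  expect_equal(prof$per_month_mean$values, rep(2, 12))
  expect_equal(prof$max_min_ratio, 1)
  expect_equal(prof$total_events, 24L)

  # January 18, July 10, all other months 12, over one year: ratio 1.8
  counts <- c(18, rep(12, 5), 10, rep(12, 5))
  ev2 <- data.frame(type = "birth", year = 1, month = rep(1:12, counts))
  prof2 <- monthly_event_profile(ev2, "birth", years_covered = 1)
  expect_equal(prof2$peak_month, 1L)
  expect_equal(prof2$trough_month, 7L)
  expect_equal(prof2$max_min_ratio, 1.8)

  # no events of the requested type: zeros with undefined ratio, not an error
  prof3 <- monthly_event_profile(ev2, "death", years_covered = 1)
  expect_equal(prof3$per_month_mean$values, rep(0, 12))
  expect_true(is.na(prof3$max_min_ratio))
})

test_that("event profile conserves counts and tracks generator intensities", {
  cfg <- synth_config(years_demography = 200, seed = 53)
  ev <- gen_demography(cfg)
  for (ty in c("birth", "death")) {
    prof <- monthly_event_profile(ev, ty, cfg$years_demography)
    expect_equal(prof$total_events, sum(ev$type == ty))  # exact conservation
    expect_equal(sum(prof$per_month_mean$values) * prof$years_covered,
                 prof$total_events, tolerance = 1e-9)
    lam <- cfg[[paste0(ty, "_intensity_by_month")]]
    se <- sqrt(lam / 200)
    expect_true(all(abs(prof$per_month_mean$values - lam) < 3.5 * se))
  }
})

test_that("z-scoring standardizes, is idempotent and preserves ranks", {
  s <- monthly_series(c(1, 2, 3, rep(NA, 9)))
  z <- zscore(s)
  expect_equal(z$values[1:3], c(-1, 0, 1))
  expect_true(all(is.na(z$values[4:12])))
  expect_equal(zscore(z)$values, z$values, tolerance = 1e-12)
  set.seed(6)
  s2 <- monthly_series(rnorm(12, 50, 5))
  expect_equal(mean(zscore(s2)$values), 0, tolerance = 1e-12)
  expect_equal(sd(zscore(s2)$values), 1, tolerance = 1e-12)
  expect_equal(spearman_rho(s2$values, zscore(s2)$values), 1, tolerance = 1e-12)
  expect_error(zscore(monthly_series(rep(5, 12))), "zero variance")
  expect_error(zscore(monthly_series(c(1, rep(NA, 11)))), "2 non-missing")
})

test_that("percent differences follow the (a - b) / b convention", {
  s <- monthly_series(c(100, 183.6, 104.9, 50, rep(NA, 8)))
  expect_equal(pct_diff(s, 2, 1), 83.6)
  expect_equal(pct_diff(s, 3, 1), 4.9, tolerance = 1e-9)
  expect_equal(pct_diff(s, 1, 1), 0)
  expect_error(pct_diff(s, 5, 1), "missing")
  expect_error(pct_diff(monthly_series(c(1, 0, rep(NA, 10))), 1, 2), "value 0")
})

test_that("monthly series survive a CSV round trip with missing slots", {
  s <- monthly_series(c(1.5, NA, 3, 4, NA, 6, 7, 8, 9, 10, 11, 12),
                      n_contributing = c(3, 0, 2, 1, 0, 5, 1, 1, 1, 1, 1, 1))
  p <- tempfile(fileext = ".csv")
  write_monthly_series(s, p)
  s2 <- read_monthly_series(p)
  expect_equal(s2$values, s$values)
  expect_equal(s2$n_contributing, s$n_contributing)
  unlink(p)
})
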