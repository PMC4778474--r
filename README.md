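# seasoncorr

Seasonal cross-correlation of monthly physiology, climate and demography.

## The problem

Long-lived animals in strongly seasonal environments — the motivating system
is the semi-captive Asian elephant population working in Myanmar's timber
industry under a monsoon climate — show month-to-month variation in
physiological markers such as faecal glucocorticoid metabolite concentration
(GCM, a non-invasive proxy for stress, in ng/g dry faeces) and body weight
(a proxy for condition, in kg). At the population level, births and deaths
are also strongly seasonal. Linking these requires comparing short
individual-level monthly panels with multi-decade demographic averages and
monthly climatologies, asking *whether* each marker varies by calendar month
and *at what time lag* it tracks rainfall, temperature, births and deaths.

`seasoncorr` implements that analysis as a reusable, tested pipeline:

1. **Synthetic study system** (`synth_config()`, `gen_climate()`,
   `gen_population()`, `gen_panel()`, `gen_demography()`): longitudinal
   panels with individual random intercepts, a single-harmonic seasonal
   signal `A cos(2π(m − peak)/12)`, stationary AR(1) month-to-month noise,
   structured missingness, and Poisson monthly birth/death streams. Every
   stage of the analysis is exercisable with no access to the (undeposited)
   registry data it emulates.
2. **Panel preparation** (`center_within_individual()`,
   `monthly_group_means()`, `monthly_event_profile()`, `zscore()`,
   `pct_diff()`): within-individual centering (value minus the individual's
   own mean, isolating within-subject seasonal variation), sex–age balanced
   monthly means (the pooled series is the unweighted mean of per-group
   means, so month-to-month changes in who was sampled cannot masquerade as
   seasonality), and mean births/deaths per calendar month with max/min
   ratios.
3. **Month-effect test** (`month_effect_test()`): a one-way F statistic on
   the centred values, calibrated by permuting month labels *within* each
   individual — exact under the null, immune to between-individual
   heterogeneity.
4. **Lagged cross-correlation** (`lagged_xcorr()`, `xcorr_significance()`,
   `build_lag_spec()`): Spearman's ρ between two 12-month series at every
   allowed lag k (pairing month m with month m + k, circular by default),
   best lag chosen by maximal |ρ|. Lag sets encode directionality: deaths
   may only follow a marker (lags 0..K), markers may only follow climate
   (0..K), births may lead or follow (−K..K, since a birth month also stands
   for a conception 22 months earlier). Significance is by permutation of
   the 12 calendar slots, reported per lag *and* selection-adjusted for the
   post-hoc choice of best lag.
5. **Pipeline + CLI** (`run_pipeline()`, `cli_main()`): generate → prep →
   seasonality → all nine variable pairs, with a deterministic Markdown +
   JSON report.

## Worked example

```r
library(seasoncorr)
cfg     <- synth_config()                 # the default study conditions
climate <- gen_climate(cfg)
pop     <- gen_population(cfg)            # 75 core + 51 weight-only adults
panel   <- gen_panel(pop, climate, cfg)   # GCM and weight, monthly

weight <- monthly_group_means(panel, "weight", c("sex", "age_group"))$pooled
res <- xcorr_significance(climate$rainfall, weight,
                          build_lag_spec("climate_vs_marker", 3),
                          n_perm = 9999, seed = 2)
res
#> Lagged Spearman cross-correlation: rainfall -> weight:pooled (circular alignment)
#>  lag   rho n_pairs p_asymptotic p_perm
#>    0 0.801      10     5.33e-03 0.0084
#>    1 0.982      10     4.77e-07 0.0001
#>    2 0.866      10     1.20e-03 0.0021
#>    3 0.489      10     1.51e-01 0.1573
#> best lag +1 (b follows a), rho = 0.982
#> selection-adjusted permutation p = 0.0001 (n_perm = 9999)
```

The generator places the weight seasonal peak one month after the rainfall
peak (forage converts to body mass with a short delay), and the analysis
recovers exactly that: the best lag is +1 — weight follows rain by one
month — with ρ = 0.98 over the 10 months in which weight is measured, and a
selection-adjusted permutation p of 1/10000, the smallest value 9999
permutations can produce. At lag 0 the correlation is lower (0.80) and lag 3
is indistinguishable from noise once the lag search is accounted for.

```r
mt <- month_effect_test(panel, "weight", n_perm = 999, seed = 2)
mt
#> Permutation month-effect test on centred weight
#>   1130 observations from 113 individuals, 10 months represented
#>   F-like statistic = 153.671, permutation p = 0.001 (n_perm = 999)
```

Weight varies by calendar month far beyond what reshuffling months within
individuals can produce (p = 1/1000, the add-one minimum).

The same analysis end to end, from the shell:

```sh
Rscript inst/cli/seasoncorr.R run --config cfg.json --out-dir out --seed 1
```

writes `report.md` / `report.json` with, for every variable pair, the best
lag, ρ, per-lag and selection-adjusted p-values, plus demographic
seasonality ratios and sex/age weight contrasts.

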