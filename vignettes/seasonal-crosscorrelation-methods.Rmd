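---
title: "Methods: seasonal cross-correlation of monthly physiology, climate and demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal cross-correlation of monthly physiology, climate and demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasoncorr)
```

## The analytical question

Given (i) a short longitudinal panel of individual physiological
measurements taken once per calendar month — faecal glucocorticoid
metabolite concentration (GCM, ng/g dry faeces) and body weight (kg) in a
semi-captive working elephant population — (ii) multi-decade monthly birth
and death counts for the whole population, and (iii) a monthly climate
climatology (total rainfall in mm, mean temperature in °C), the analysis
asks two questions:

1. Does each marker vary by calendar month beyond what stable individual
   differences and sampling noise can explain?
2. At what time lag, and how strongly, does each marker's seasonal profile
   track rainfall, temperature, births and deaths?

Both questions are answered on 12-slot calendar-month series
(`monthly_series`), the package's universal unit.

## Within-individual centering and balanced aggregation

Repeated measures of the same animal are correlated: some elephants run
high GCM or heavy body weight throughout. `center_within_individual()`
decomposes each animal's series into its own mean and month-specific
deviations (value − own mean). The deviations carry all the within-subject
seasonal signal and none of the between-subject heterogeneity; they sum to
zero exactly for every individual, which the test suite checks as an
invariant. We use the standard deviation-from-own-mean sign; a `negate`
flag provides the mirrored convention, which changes only signs, never
magnitudes. Individuals observed in fewer than two months carry no
within-individual information; they are dropped from centering (with a
warning) but still contribute to monthly means.

Population-level monthly profiles come from `monthly_group_means()`. The
pooled series is deliberately the **unweighted mean of per-group (sex ×
age-class) monthly means**, not the raw grand mean: the number of animals
measured per month differs by group (weight, for instance, is measured in
only part of the roster and not at all in two months), and a raw mean would
confound those composition shifts with seasonality. The balanced mean holds
group composition constant by construction. Months with no data propagate
as missing; nothing is imputed, and the cross-correlation stage deletes
incomplete month pairs pairwise.

## The permutation month-effect test

The original analysis fit linear mixed models with ARMA residual
correlation to test for a month effect. This package instead tests the
centred values directly: the statistic is the classical one-way F ratio
(between-month mean square over within-month mean square) of centred
values grouped by calendar month, and its null distribution is obtained by
randomly permuting the month labels **within each individual**. The
permutation preserves each animal's set of values (and its zero mean) while
destroying seasonal alignment, so the test is exact when the within-animal
values are exchangeable under the null, regardless of how large the
between-animal variance is. On a balanced panel with no individual effects
the statistic reduces to the classical one-way ANOVA F, which the tests
verify against an independent `lm()`/`anova()` computation to 1e-9.

P-values use the add-one estimator `(1 + #{null ≥ observed})/(1 + n_perm)`,
so the smallest attainable value is `1/(n_perm + 1)` and zero p-values are
impossible. No degrees of freedom are attached: the statistic is calibrated
by permutation and reported descriptively. Exchangeability is deliberately
the null model here: month-to-month autocorrelation within the year is a
form of seasonal structure, and the calibration simulations in the test
suite therefore run the null at `ar1_phi = 0` (pure noise).

## Lagged Spearman cross-correlation

`lagged_xcorr()` correlates series *a* at month *m* with series *b* at
month *m + k* for every allowed lag *k*; **k > 0 means b follows a**. The
convention is stated once and used everywhere, because informal phrases
like "lagged by 3 months" are ambiguous about direction. Correlations are
Spearman's ρ — Pearson on midranks, computed from first principles and
checked against base R's implementation to 1e-12 on a thousand random
vectors including ties — because 12-point monthly series are short,
non-normal and sometimes clipped (rainfall has a dry-season floor), and
rank correlation is invariant to any monotone transform (another tested
invariant).

Design choices that were genuinely open:

* **Alignment.** Default `circular`: the series are climatologies or
  multi-year averages of calendar months, for which December→January
  adjacency is physically real. A `truncated` mode (drop months shifted out
  of 1..12) is provided for sensitivity analysis. Both modes are verified
  against a naive pair-construction oracle at every lag.
* **Best lag.** The lag maximizing |ρ|, because strong *negative*
  correlations (markers versus births and deaths) are substantive findings,
  not noise. Ties break toward the smaller |lag| (parsimony), then the more
  negative lag; the tie-break is pinned by a test with an exactly periodic
  series.
* **Lag direction constraints.** `build_lag_spec()` encodes assumptions
  about causes preceding effects: deaths may only follow a marker (lags
  0..K), a marker may only follow climate (0..K), while births get the full
  −K..K window because a birth month equally represents a conception
  22 months earlier — `conception_month()` maps one to the other (a January
  birth implies a March conception, 22 months before). Default `K = 3`
  months, configurable.
* **Significance.** The null permutes the 12 calendar slots of series *b*
  with *a* held fixed. Per-lag two-sided p-values are reported alongside
  `p_selected`, the tail probability of `max_k |ρ_k|`, which accounts for
  choosing the best lag post hoc. The calibration test demonstrates both
  that `p_selected` rejects at the nominal 5% rate on independent series
  and that taking the smallest per-lag p without adjustment over-rejects.
  A t-approximation p per lag is reported for comparison only; with n = 12
  it is crude. When both series are complete and alignment is circular, the
  permutation loop uses a rank-rotation identity (ranks of a permuted
  vector are the permuted ranks, and every lag uses all 12 pairs) that
  reduces each permuted ρ to an inner product; otherwise a general path
  reconstructs and re-ranks the pairs per permutation. Both paths produce
  identical statistics by construction; the fast path is itself validated
  against the observed-statistic route.

## The synthetic study system

The registry data the analysis was designed for are not publicly
deposited, so the package ships a generator whose defaults *are* the study
conditions, and the whole pipeline is tested on what it produces.

For individual *i*, variable *v* and calendar month *m*:

value = baseline_v(sex, age group) + b_i + A_v · cos(2π(m − peak_v)/12) + ε_m,

with `b_i ~ N(0, σ²_ind,v)` and ε a stationary AR(1) process with
coefficient φ and innovation SD `σ_noise,v`. Defaults, with reasoning:

| parameter | default | why |
|---|---|---|
| core individuals | 75 (43 female) | the GCM sampling design |
| weight-only adults | +51 | auxiliary-camp weighing; 116 weighed animals in total |
| age classes | 0–16 / 17–44 / 45+ at 15/55/30% | juvenile, prime working, old/retired |
| GCM baseline, amplitude, peak | 55 ± 15 ng/g, July | amplitude gives a wet/dry contrast of the reported order; July centres the June–August elevated period, in phase with monsoon rain |
| weight baseline, amplitude, peak | 2500 ± 50 kg, September | a few-percent seasonal swing; one month after the rain peak (forage → condition with a short delay) |
| male / old multipliers | 1.259 / 1.075 | the reported sex and age contrasts, as config not constants |
| σ_ind | 12 ng/g / 150 kg | large between-animal spread in hormones, proportionally small in weight |
| φ, σ_noise | 0.3; 8 ng/g / 35 kg | consecutive months similar; the original ARMA order and variance components are unreported, so AR(1) is the minimal configurable structure (φ = 0 disables it) |
| weight missing months | August, November | the study's gaps |
| rainfall | 0–320 mm, peak August, shape 1.5 | monsoon June–October, dry-season zero; range configurable up to the recorded 0–906 mm extremes |
| temperature | 25 ± 5 °C, peak May | hot season immediately before monsoon onset |
| births | ~40/yr, peak January, max/min 1.8 | cool-dry birth peak, July trough |
| deaths | ~18/yr, peak January, trough November, ratio 2.0 | deaths at dry/cool extremes; an explicit 12-vector because a single cosine cannot peak in January *and* trough in November |
| demography span | 57 years | multi-decade averaging |

GCM values are floored at zero (concentrations cannot be negative); under
the defaults the additive Gaussian model dips below zero for well under
0.1% of observations, and the noise-free and autocorrelation-recovery
tests use settings where the floor never triggers. Demography is generated
as independent Poisson monthly counts, not individual life histories — the
analysis consumes only monthly counts. Climate is deterministic given the
configuration (a climatology has no sampling noise). All generators are
bit-reproducible given the config seed; stage streams inside the pipeline
derive from it by fixed small offsets.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no pregnancy or workload effects, no
camp-to-camp differences beyond labels, no climate→physiology causal path
(the seasonal signal is parameterized directly, so climate–marker
correlations in generated data reflect phase alignment, not response), no
long-term trends or between-year variance, and no dependence between
births, deaths and the sampled individuals. Single-harmonic seasonality is
the minimal shape giving lag-recovery tests a well-defined truth; real
profiles can be skewed or bimodal.

## Numerical and degenerate-input conventions

* Spearman needs ≥ 3 complete pairs and nonzero rank variance; lags
  failing this are dropped with a warning, and an error is raised only if
  no allowed lag survives. In the permutation loop a lag that becomes
  degenerate under a permutation counts as an exceedance (conservative).
* Equality comparisons in permutation counting use a 1e-12 guard so that
  ties between the observed and a permuted statistic count as exceedances.
* ρ is clipped to [−1, 1] against floating-point fuzz.
* Z-scoring (`zscore()`) requires ≥ 2 non-missing slots and nonzero
  variance, uses the n−1 SD, and leaves missing slots missing.
* `pct_diff()` errors on a missing month or zero reference rather than
  returning infinities. A zero-event demographic profile reports an
  undefined (missing) max/min ratio, not an error.
* Pipeline reports (`report.md`, `report.json`) contain no timestamps or
  absolute paths, so identical config + seed reproduces them byte for
  byte; the run manifest carries timestamps and is the only
  non-reproducible output.

## Problem sizes in the test suite

The suite exercises the oracle equivalences at full prescribed volume
(1000 random vectors for Spearman, 500 series for the lag oracle, since
both run in seconds), permutation calibrations at 500–1000 replicate
datasets with 199–999 permutations each (permutation tests are exact at
any permutation count, so replicate volume governs only the precision of
the estimated rejection rate), Monte-Carlo variance checks on 2500
simulated individuals, and lead-recovery on 200 freshly generated
study-sized datasets. End-to-end determinism is checked on a reduced
roster (20 + 10 individuals, 30 years of demography), which exercises every
stage and file format identically.

## Known limitations

* The month-effect permutation test assumes within-individual
  exchangeability under the null; with strong residual autocorrelation its
  level is not guaranteed. The substitution of this test for the original
  mixed-model/ARMA route is the package's largest methodological departure,
  made because the centred-value analysis is the robustness check the
  original design itself relied on.
* Circular alignment treats the 12-month profile as a cycle; for a single
  observed year (rather than a climatology) truncated alignment may be more
  defensible, and both are provided because the original choice is
  unstated.
* With n = 12 slots, permutation p-values have a resolution floor of
  `1/(n_perm + 1)` and the lag search spans at most ±3 months by default;
  finer temporal structure is not identifiable from monthly data.
* Whether published monthly means were raw cell means or model-adjusted
  values is unstated; the package provides balanced (composition-controlled)
  and per-group raw means, but does not extract model coefficients.
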