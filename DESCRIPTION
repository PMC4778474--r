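Package: seasoncorr
Title: Seasonal Cross-Correlation of Monthly Physiology, Climate and
    Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking seasonal variation in individual physiological
    markers (faecal glucocorticoid metabolites, body weight) to monthly
    climate and population-level birth and death seasonality. Provides a
    synthetic longitudinal data generator (individual random intercepts,
    AR(1) month-to-month noise, monsoon-phased seasonal signals, Poisson
    demographic event streams), within-individual centering and sex-age
    balanced monthly aggregation, a permutation test for calendar-month
    effects on repeated measures, and sign-constrained lagged Spearman
    cross-correlation with best-lag selection and permutation significance,
    together with an end-to-end pipeline runner and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
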