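Package: invasim
Title: Disturbance-Mediated Microbial Invasion: Fitness Metrics, Inference
    and Serial-Transfer Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pulse-disturbance invasion experiments in
    bacterial microcosms. Converts morphotype plate counts to densities,
    computes the relative-fitness ratio v of invader proportional change
    (with invasion-event averaging of the initial invader proportion and
    mortality-based imputation of unmeasured resident densities), Simpson's
    diversity and log-scaled resident density, and runs the full linear-model
    battery (disturbance-by-resource-by-invader interactions, type III/II
    ANOVA, likelihood-ratio model selection, per-resource slopes with
    confidence intervals, Bonferroni-adjusted marginal comparisons). A
    mechanistic serial-transfer microcosm simulator and a parametric response
    generator provide fully synthetic test data with known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    jsonlite,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
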