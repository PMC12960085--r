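Package: ventcost
Title: Modeling the Oxygen Cost of Ventilation During Ramp-Incremental Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the oxygen cost of ventilation (VO2vent)
    during ramp-incremental cycle exercise from six routinely measured
    predictors (peak expired ventilation, age, weight, height, VO2 peak and
    maximal heart rate). Implements a published 16-constant composite
    non-linear model and its six single-predictor sub-models, refits the
    composite form to new cohorts by profiled least squares, and provides
    internal validation (leave-one-out cross-validation, bootstrap
    resampling, calibration and collinearity diagnostics). Applies a
    coefficient set to breath-by-breath ramp-test series to produce
    ventilation-corrected oxygen-uptake trajectories, percent-of-peak-power
    intensity tables, final-window slope analyses, paired slope tests and
    Greenhouse-Geisser-corrected repeated-measures ANOVA. Includes a seeded
    generator of synthetic cohorts and breath-by-breath ramp tests, plus
    BTPS-to-STPD gas-volume conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
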