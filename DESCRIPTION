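Package: abcscore
Title: Validation Toolkit for the ABC Out-of-Hospital Cardiac Arrest
    Prognostic Score
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes and validates the ABC (Age, Bystander, Cardiogram)
    prognostic score for out-of-hospital cardiac arrest patients without
    prehospital return of spontaneous circulation. Provides Utstein-style
    registry input/output with configurable dialects, guideline-period
    cohort selection with an auditable exclusion log, score-stratum
    contingency tables (including reconstruction from cumulative threshold
    counts), diagnostic test characteristics with pluggable binomial
    confidence intervals, tie-corrected ROC/AUROC for ordinal scores,
    Youden-index cutoff selection, calibration tables, and a seeded
    synthetic registry generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
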