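Package: pedvitals
Title: Age-Based Vital-Sign Cutoffs for Pediatric Major Trauma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and evaluating age-adjusted vital-sign
    cutoffs that identify major trauma in children. Provides an encounter
    data model with an eligibility exclusion cascade, the PALS and ATLS
    vital-sign rule tables plus an empirically derived age-banded table,
    age-varying z-score transforms for heart rate, respiratory rate and
    systolic blood pressure, two-sided Youden-optimal cutpoint derivation
    on median-split ROC curves, composite trauma outcome construction
    (Cribari matrix, NFTI, NEI-6, STAT), diagnostic accuracy reports with
    confidence intervals, paired AUROC comparison, spline risk curves and
    calibration summaries, and a synthetic trauma-registry generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
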