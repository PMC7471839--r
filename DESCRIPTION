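Package: adnexrisk
Title: Diagnostic Risk Models for Adnexal Masses in Postmenopausal Women
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and comparison of diagnostic prediction models for
    ovarian cancer in postmenopausal women presenting with an adnexal mass.
    Implements Firth bias-reduced logistic regression, chained-equation
    multiple imputation of missing ultrasound variables with Rubin's-Rules
    pooling, imputation-aware stratified k-fold cross-validation, the ROMA
    and modified Risk of Malignancy Index comparator scores, and a full
    diagnostic-accuracy evaluation suite (AUC with DeLong comparisons,
    sensitivity at fixed specificity, McNemar tests, bias-corrected
    bootstrap confidence intervals, predictive values at arbitrary
    prevalence, Brier score, Hosmer-Lemeshow calibration). A synthetic
    cohort generator calibrated to the published marker and morphology
    distributions of the UKCTOCS adnexal-mass cohort makes every stage of
    the pipeline testable end to end.
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
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
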