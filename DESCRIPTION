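Package: muacscreen
Title: Diagnostic Accuracy of Mid-Upper Arm Circumference for Adolescent Overweight Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates mid-upper arm circumference (MUAC) as a screening marker
    for overweight and obesity in adolescents against a BMI-for-age Z-score
    reference. Provides replicate-measurement preprocessing with LMS growth
    reference Z-scores, empirical ROC analysis with DeLong confidence
    intervals and Youden-index optimal cutoffs, a full diagnostic-metric panel
    (sensitivity, specificity, predictive values, likelihood ratios) with
    exact binomial and log-method confidence intervals, internal validation by
    bootstrap optimism correction of the AUC, Hosmer-Lemeshow calibration
    assessment, Spearman rank-correlation analysis, and a Gaussian-copula
    synthetic cohort generator for fully reproducible end-to-end pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
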