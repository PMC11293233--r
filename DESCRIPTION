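Package: pesicu
Title: Validation of Pulmonary Embolism Mortality Risk Scores in the ICU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating mortality risk prediction scores in
    critically ill patients who develop pulmonary embolism after ICU
    admission (secondary PE). Provides deterministic calculators for the
    Pulmonary Embolism Severity Index (PESI), the simplified PESI (sPESI)
    and the ICU-adapted sPESI (ICU-sPESI) with their risk classes;
    reduction of raw vital-sign time series to per-patient worst-case
    values via 30-minute window medians; cohort inclusion/exclusion rules
    for secondary PE; a latent-severity synthetic cohort generator for
    testing every downstream stage without access-controlled ICU data;
    univariate logistic calibration, AUROC estimation with the
    Hanley-McNeil standard error and paired comparison of correlated
    AUROCs; Wald binomial confidence intervals; Kaplan-Meier survival
    curves with multi-group and Bonferroni-corrected pairwise log-rank
    tests; and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
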