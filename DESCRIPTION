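Package: cltriage
Title: Cervical-Length Screening Triage for Pregnancies After Cervical Conization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal second-trimester cervical-length (CL)
    surveillance in pregnancies following excisional cervical treatment (conization)
    for CIN. Implements a three-step rule-based triage model that classifies each
    screening visit as high-risk, discharge, or continue; a constrained derivation
    procedure (threshold grid search plus recursive partitioning) with
    leave-one-hospital-out validation; diagnostic-accuracy threshold sweeps over CL
    and percentage CL change (sensitivity, specificity, predictive values,
    likelihood ratios, ROC); contingency statistics for the suture-material
    comparison (Katz relative risk, exact tests, rank tests); scan-utilisation
    accounting; and a calibrated synthetic-cohort generator for testing the whole
    pipeline without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
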