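Package: ntscore
Title: New Trauma Score (NTS) Calculation, Derivation and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for physiological trauma severity scoring built around the
    New Trauma Score (NTS), a modification of the Revised Trauma Score that
    uses the actual Glasgow Coma Scale score, recalibrated systolic blood
    pressure intervals and peripheral oxygen saturation in place of
    respiratory rate. Provides the published code-value maps and scoring
    equations (RTS, NTS, predicted survival, the unweighted T-NTS triage sum,
    and the MGAP and GAP comparators), registry readers and writers with
    validation, a calibrated synthetic trauma-registry generator, chained
    multiple imputation with predictive mean matching, and the statistical
    machinery used to derive and validate such scores: logistic model fitting,
    odds ratios, ROC areas with DeLong's test for correlated curves,
    Hosmer-Lemeshow calibration, and triage operating-point analysis.
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
    pROC
Config/testthat/edition: 3
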