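Package: polyptriage
Title: Non-Invasive Risk Stratification for Colorectal Polyp Surveillance
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for evaluating non-invasive triage strategies in
    colorectal polyp surveillance, built around two markers: a urinary
    volatile organic compound (VOC) classifier score and the quantitative
    faecal immunochemical test (FIT, ug Hb/g faeces). Provides
    threshold-sweep diagnostic accuracy (sensitivity, specificity,
    predictive values with Wilson or Clopper-Pearson intervals), empirical
    ROC operating points with trapezoidal AUC, the likelihood-ratio
    (Fagan nomogram) calculus for single tests and serial or parallel
    combinations, per-1000-patient cohort-flow accounting with
    number-needed-to-scope, a seeded k-fold cross-validation harness with
    an injectable scorer, and a quantile-calibrated synthetic cohort
    generator so that every stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pROC, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
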