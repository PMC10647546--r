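Package: nutriscreen
Title: Evaluation Pipeline for an EMR-Based Pediatric Nutrition Screening Tool
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an executable rule engine for a daily, electronic
    medical record based pediatric nutrition screen (the Children's Wisconsin
    Nutrition Screening Tool): element predicates and thresholds, age-based
    anthropometric z-score dispatch, the any-positive aggregation rule and the
    status-change screening schedule. Provides severity-stratified
    diagnostic-accuracy statistics (sensitivity, specificity, predictive
    values, Fisher's exact association tests, contingency reporting), a
    cost-sensitive misclassification penalty score with exhaustive best-subset
    selection over screen elements, and a calibrated synthetic PICU cohort
    generator standing in for patient-level data that cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
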