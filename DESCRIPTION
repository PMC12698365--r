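Package: crekid
Title: One-Day Urinary Creatinine Excretion Prediction in Schoolchildren
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating one-day (24-hour) urinary creatinine
    excretion in school-aged children from anthropometry and spot-urine
    measurements. Provides a battery of published prediction equations,
    Bland-Altman method agreement with trend-bias decomposition, a
    trend-bias recalibration operator for linear estimators, Lasso-based
    feature ranking with cross-validated subset search and ordinary
    least-squares model fitting, spot-urine sodium excretion estimation
    via the Tanaka power equation, LMS growth z-scores, and a seeded
    synthetic cohort generator with void-level urine records so the full
    workflow is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
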