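Package: cssi
Title: Confined-Space Suitability Index Construction and Internal Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and internally validates the Confined-Space Suitability
    Index (CSSI), an additive 0-100 fitness-for-duty screening score for
    confined-space work. Thirteen dichotomous health risk factors are coded
    from routine health-examination records using tiered clinical cutoffs,
    weighted by truncated and normalized coefficients from an L1-penalized
    logistic regression of the rule-based unsuitable classification, and
    summed into a score. Includes a seeded synthetic cohort generator with
    configurable Gaussian-copula correlation, leave-one-out cross-validated
    discrimination metrics (AUROC, AUPRC, confusion-matrix statistics), and
    bootstrap selection-frequency stability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
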