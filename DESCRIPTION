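Package: sitiscale
Title: The Surgical Intervention for Traumatic Injury (SITI) Scale and Its
    Diagnostic Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Surgical Intervention for Traumatic Injury (SITI)
    scale, a five-component additive score (0-11 points) that communicates
    the potential need for surgical decompression (craniotomy or
    craniectomy) after traumatic brain injury. Components are the Glasgow
    Coma Scale total, the pupil examination, and three head-CT findings:
    midline shift, temporal (middle cranial fossa) pathology, and epidural
    hematoma width. Alongside the scoring rules the package provides the
    full diagnostic-evaluation workflow for a labeled patient cohort
    (confusion matrix at a score threshold, sensitivity, specificity,
    predictive values, ROC curve and trapezoidal AUC, two-group
    comparisons, and logistic models of surgery odds on component subsets),
    a documented CSV cohort schema with validation and exclusion
    accounting, and a seeded synthetic-cohort generator calibrated to
    published group marginals so the whole pipeline is testable without
    access to the original trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
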