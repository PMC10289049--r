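Package: ldlcompare
Title: Comparison of Closed-Form LDL Cholesterol Estimation Equations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a registry of 23 published closed-form equations for
    estimating low-density lipoprotein cholesterol (LDL-C) from a standard
    lipid panel (total cholesterol, HDL-C, triglycerides), including the
    fixed-ratio Friedewald family, linear models, the Martin/Hopkins
    adjustable-factor lookup (standard and extended-triglyceride variants),
    and quadratic/interaction equations such as Sampson. Provides
    guideline-category concordance analysis against a reference LDL-C,
    patient-level error summaries, upward-reclassification analysis at
    treatment thresholds, declarative clinical subgroup strata, and a
    calibrated synthetic lipid-panel cohort generator for end-to-end testing
    of the evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
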