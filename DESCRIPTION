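Package: labconcord
Title: Concordance of Diagnosis-Code Labels with Laboratory-Based Severity
    Labels in Hospital Admissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing how well diagnosis codes recover
    laboratory-defined clinical outcomes in inpatient cohorts. Builds nested
    lab-based severity labels (abnormal via institution- and age-specific
    reference ranges; mild, moderate and severe via configurable thresholds)
    and diagnosis-code labels per admission, quantifies their agreement with
    Cohen's kappa, sensitivity and specificity, estimates institution odds
    ratios with patient-level random-intercept logistic regression (99.9%
    Wald intervals), compares per-hospital-unit weighted label proportions
    with Spearman correlation, and ships a seeded two-institution synthetic
    EHR generator with closed-form expected metrics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
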