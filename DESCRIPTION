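Package: rfprofile
Title: Subgroup Discovery for Renal Function Preservation in Confounded
    Observational Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers and validates patient profiles (conjunctions of at
    most two clinical criteria) in which one antidiabetic drug class shows
    superior renal function preservation versus a comparator in confounded
    observational data. Provides a synthetic claims-style cohort generator
    with known confounding and implanted benefit subgroups, eligibility
    filtering with an attrition log, creatinine-based eGFR derivation,
    propensity-score adjusted logistic and Gaussian effect models,
    exhaustive rule enumeration over quantile grids with four credibility
    screening indicators, and stratified hold-out validation with
    Benjamini-Hochberg multiple-testing control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
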