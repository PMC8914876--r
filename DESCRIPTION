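Package: roadtbi
Title: Traumatic Brain Injury Risk from Road Traffic Collision Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline linking road traffic collision dynamics to
    traumatic brain injury (TBI) outcomes. Extracts TBI pathology and
    symptoms from clinical free text with a lexicon-driven search and
    negation filtering, assigns Mayo severity classes, computes vehicle and
    vulnerable-road-user delta-V and study eligibility, produces prevalence
    tables, relative risks and the associated nonparametric and contingency
    tests, scales in-depth sample estimates to national casualty totals with
    post-stratification weights, and fits bootstrapped cumulative delta-V
    distributions and cross-validated logistic injury-risk curves with ROC
    AUC. Ships a synthetic cohort generator with known ground truth so every
    stage is testable without access-restricted collision databases.
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
    optparse
Config/testthat/edition: 3
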