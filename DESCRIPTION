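Package: pharmscreen
Title: Drug-Wide Survival Screening with Stabilized IPTW and Path-Specific
    Mediation for Claims Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens many concomitant medications for association with
    overall and disease-free survival in observational claims cohorts.
    Codes chronic drug exposure from dispensing streams, adjusts for
    confounding by stabilized inverse-probability-of-treatment weighting
    with a standardized-mean-difference balance gate, estimates marginal
    hazard ratios by weighted Cox regression with robust Wald inference,
    decomposes significant effects into path-specific effects through tumor
    subtype and nodal status by mediator-probability-ratio weighting,
    corrects for multiple testing with Benjamini-Hochberg, and reports
    weighted Kaplan-Meier curves with an adjusted log-rank test. Includes a
    synthetic claims generator with an explicit structural causal model and
    Monte-Carlo oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    nnet,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
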