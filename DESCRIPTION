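Package: synthpanel
Title: Sequential CART Synthesis and Utility Evaluation for Longitudinal
    Athlete Monitoring Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for generating and evaluating synthetic versions of
    longitudinal athlete-monitoring panels (weekly acute load, uncoupled
    chronic load, and binary injury indicators). Implements sequential
    synthesis with classification and regression trees under a set of
    named predictor-specification conditions and two chronic-load
    scenarios, propensity-score global utility metrics (pMSE, s-pMSE,
    PO50), replication of a logistic generalized estimating equation
    injury analysis with exchangeable working correlation as a specific
    utility measure, a calibrated panel simulator for testing the full
    pipeline, and a study harness that aggregates utility metrics across
    replicate syntheses and emits release documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    sandwich
Config/testthat/edition: 3
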