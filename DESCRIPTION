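Package: smart2risk
Title: Competing-Risk Estimation and Validation of 10-Year Recurrent ASCVD Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving, applying, recalibrating and validating the
    SMART2-style 10-year risk score for recurrent atherosclerotic
    cardiovascular disease (ASCVD) in patients with established vascular
    disease. Provides a Fine-Gray subdistribution-hazard estimation engine
    with inverse-probability-of-censoring weighting and fixed offset terms,
    the 13-predictor scoring function with an antithrombotic offset and
    regional baseline-hazard recalibration via expected/observed ratios,
    competing-risk-adjusted discrimination and calibration metrics with
    random-effects pooling, competing-risk decision-curve analysis, and a
    seeded synthetic cohort simulator for the derivation-cohort conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    metafor,
    optparse
Config/testthat/edition: 3
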