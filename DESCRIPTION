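Package: glycotool
Title: Simulation and Analysis Pipeline for Digital Lifestyle Intervention
    Trials on Glycemic Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to emulate and analyse a randomized-then-observational
    evaluation of a digital lifestyle intervention in type 2 diabetes.
    Provides a synthetic cohort generator with registry controls and a
    behaviour-change-technique (BCT) theme catalog; bioimpedance body
    composition (Geneva fat-free-mass and Sun total-body-water equations)
    and IPAQ physical-activity conversions; classification of longitudinal
    HbA1c trajectories into sustained and oscillatory progression patterns;
    quarterly exposure-response binning and weighted BCT responder scoring;
    exact-sex Mahalanobis matching against a registry pool, three
    inverse-probability weighting schemes with gradient-boosted propensity
    scores and sandwich standard errors, bootstrap mediation decomposition,
    and power and sample-size calculations for two-group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    sandwich,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
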