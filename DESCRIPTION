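Package: occupair
Title: Two-Species Conditional Occupancy Models and Species Interaction
    Factors for Detection/Non-Detection Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-season occupancy models with imperfect detection for
    detection/non-detection survey data, in single-species and conditional
    two-species (dominant/subordinate) parameterizations.  Fits
    logit-linked covariate models for occupancy and detection by maximum
    likelihood, computes species interaction factors (SIF) with
    delta-method standard errors, ranks models by AIC with Akaike weights
    and candidate sets, simulates surveys for power and recovery checks,
    and orchestrates the hierarchical prey-occupancy-as-covariate analysis
    pipeline used in large-carnivore spoor transect studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
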