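Package: emodyad
Title: Dyadic Daily-Diary Emodiversity and Actor-Partner Interdependence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing caregiver-adolescent daily-diary emotion data.
    Builds per-person mean positive/negative emotion and Gini-based emodiversity
    scores from 14-day diaries of 16 ordinal emotion items, applies the standard
    sample-exclusion rules for reliable emodiversity calculation, and links the
    resulting emotion features to anxious and depressive symptoms through
    bivariate actor-partner interdependence models (APIM) estimated by
    full-information maximum likelihood with sandwich robust standard errors,
    standardized coefficients, multigroup stratification, and conditional-effect
    (simple-slopes) curves for mean-emotion by emodiversity interactions. A
    synthetic-data generator with known statistical structure makes every stage
    of the pipeline testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    lme4,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
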