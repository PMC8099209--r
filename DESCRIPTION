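Package: adforecast
Title: Autoregressive Ordinal Mixed Models for Daily Atopic Dermatitis
    Severity Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess whether environmental exposures improve
    short-term prediction of daily atopic dermatitis (AD) severity. Fits
    mixed-effect autoregressive ordinal logistic regression models to
    daily 0-4 sign scores (dryness, oedema, itching, oozing, redness,
    sleep disturbance) with patient random intercepts estimated by
    adaptive Gauss-Hermite quadrature, validates forecasts by forward
    chaining against uniform and historical benchmarks under the ranked
    probability score, derives probabilistic binary symptom-state
    forecasts from the six per-sign models, and compares covariate
    ablations. Includes a calibrated synthetic cohort generator for
    longitudinal ordinal panel data with seasonal environmental series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    pracma,
    Rcpp,
    sandwich,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
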