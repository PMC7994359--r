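Package: smokecast
Title: Wildfire Smoke Exposure and Syndromic Health Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular pipeline for forecasting the population health
    impacts of wildfire smoke. Blends numerical smoke-forecast PM2.5
    fields with observation-based predictors (monitors, aerosol optical
    depth, fire radiative power, smoke-plume flags, venting index) using
    random forests, aggregates exposure to administrative health areas by
    population weighting, forecasts a syndromic indicator (reliever
    inhaler dispensations) from exposure plus temporal features, and
    verifies forecasts with RMSE, the index of agreement, and
    within-tolerance fractions. Includes a seeded synthetic smoke-season
    generator so the whole pipeline runs end-to-end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
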