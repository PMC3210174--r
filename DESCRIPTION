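Package: bloomcast
Title: Chill-Day Phenology Modelling and Peak Bloom Date Projection for
    Flowering Cherries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the peak bloom dates (PBD) of temperate
    flowering cherries from daily maximum and minimum air temperature using
    a two-stage chill-day / anti-chill-day dormancy model. The package reads
    and quality-screens daily station weather and observed bloom records,
    assembles October-to-June dormancy seasons, accumulates chill days
    towards a chilling requirement and anti-chill days towards a heating
    requirement, calibrates the cultivar parameters (threshold temperature,
    chilling requirement, heating requirement) against observed bloom dates
    by grid search with local refinement minimising RMSE, evaluates model
    fit (RMSE, MAE, bias, r-squared), temporally downscales monthly climate
    normals to a daily climatology by exact trigonometric interpolation,
    and projects bloom-date shifts under climate scenarios with tabular
    summaries. A synthetic-data generator provides station-like weather and
    forward-model bloom observations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
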