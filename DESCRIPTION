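Package: gullcast
Title: Weather-Driven Daily Observation Forecasts for a Vagrant Arctic Seabird
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two coupled forecast systems for the daily observation
    probability of a rare vagrant seabird (Ross's Gull) at coastal sites on
    the Sea of Okhotsk, driven by gridded meteorological fields.  Method A
    classifies daily winter sea-level-pressure patterns with a 4x4
    self-organizing map, attaches empirical sighting probabilities to each
    node, and forecasts by Euclidean best-matching-unit lookup.  Method B
    integrates backward air-parcel trajectories through gridded winds,
    extracts lagged latitude and bearing covariates plus sea-ice extent, and
    forecasts through an AIC-selected binomial GLM on scaled covariates.
    Includes gridded-field I/O and interpolation, sighting-record
    de-duplication and effort filters, a dynamically coherent synthetic
    weather and sighting generator, and a 1-5-day-lead forecast driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
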