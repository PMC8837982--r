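Package: teagrowth
Title: Soil-Driven Tea Plantation Growth Monitoring with NDVI, Growth-Response
    Regression and a BES-Tuned LSTM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for monitoring perennial crop growth from
    in-situ soil sensing. Reconstructs a cloud-contaminated NDVI time series
    with an upper-envelope Savitzky-Golay filter, aggregates 10-minute soil
    temperature, moisture and electrical-conductivity logs to satellite
    revisit epochs, builds cumulative exposure features analogous to growing
    degree days, fits polynomial and power growth-response models with the
    matching degrees-of-freedom metric conventions, and tunes a minimal
    single-layer LSTM regressor with a Bald Eagle Search metaheuristic.
    Includes a synthetic-data generator with known ground-truth response
    parameters for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
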