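Package: socforest
Title: Space-Time Quantile Forests for Soil Organic Carbon Density Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale framework for three-dimensional plus time (3D+T)
    modelling of soil organic carbon density (SOCD, kg/m3). Harmonizes
    heterogeneous point soil records (SOC, bulk density, coarse fragments,
    analytical method) into SOCD, fits a joint mean and quantile random
    forest that retains per-tree terminal-leaf response distributions,
    aggregates predictions over spacetime blocks, selects features by
    repeated-subsampling cumulative importance, validates predictions and
    prediction intervals (PICP, PIW, QCP, accuracy curves), scores
    extrapolation risk with an isolation forest, and propagates pixel-level
    uncertainty to regional aggregates through a variogram of standardized
    residuals. Includes a synthetic 3D+T data generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
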