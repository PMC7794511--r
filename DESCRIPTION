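Package: pipomort
Title: Drone-Survey Pipeline for Bark-Beetle-Induced Ponderosa Pine Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse western pine beetle (Dendroctonus brevicomis)
    induced mortality of ponderosa pine (Pinus ponderosa) from individual-tree
    survey data.  The pipeline runs from stem maps and canopy-height rasters
    through plot-level forest-structure metrics, tree-detection benchmarking,
    crown-level spectral classification, height and allometric calibration, and
    aggregation to 20 x 20 m grid cells, up to a zero-inflated binomial
    regression with a per-site spatial Gaussian process fitted by Markov chain
    Monte Carlo.  A synthetic-data generator reproduces the statistical
    structure the model assumes (climatic-water-deficit gradient across sites,
    spatially autocorrelated mortality, zero-inflated counts) so that every
    stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
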