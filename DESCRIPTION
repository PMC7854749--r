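Package: hiercrop
Title: Hierarchical Crop-Type Mapping from Regularized Satellite Image Time Series
Version: 1.0.0
Authors@R:
    person("Hiercrop", "Developers", email = "hiercrop@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a hierarchical crop-type
    mapping pipeline for Sentinel-2-like reflectance time series: simplified
    cloud screening and seven spectral vegetation indices; 10-day median
    compositing, linear gap filling and Savitzky-Golay smoothing; banks of
    spectral-temporal, texture (gray-level co-occurrence matrix) and harmonic
    regression features; impurity-based feature selection with Spearman
    correlation clustering; random forest classification (cropland mask, then
    rice/maize/soybean typing) against spectral angle and spectral correlation
    mapper baselines; small-patch despeckling; and thematic-map accuracy
    assessment. A synthetic scene generator with crop-specific phenology
    (rice flooding signal, maize/soybean red-edge separation) stands in for
    the satellite archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
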