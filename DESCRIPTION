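Package: laitex
Title: Maize Leaf Area Index Estimation from Multispectral Imagery Using
    Spectral and Textural Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for plot-scale estimation of
    maize leaf area index (LAI) from multiband reflectance imagery. Extracts
    per-plot band reflectances and eight vegetation indices, computes
    gray-level co-occurrence matrix (GLCM) texture statistics as windowed
    texture maps, constructs normalized-difference, ratio and difference
    texture indices over all ordered feature pairs and screens them by
    correlation with LAI, then compares support vector machine, random
    forest, neural network and partial least squares regressions under
    ten-fold cross-validation with R2, RMSE and RPD. Includes a synthetic
    multispectral scene generator (Beer-Lambert two-endmember canopy mixing
    over a spatially correlated gap field) so the whole analysis runs and is
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    mgcv,
    mixOmics,
    nnet,
    ranger,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
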