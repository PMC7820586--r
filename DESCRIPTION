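Package: spatrisk
Title: Spatial Disease-Susceptibility Mapping with Frequency-Ratio Weighted
    Random Forests
Version: 0.1.0
Authors@R:
    person("spatrisk", "developers", email = "spatrisk@example.org",
           role = c("aut", "cre"))
Description: End-to-end geospatial pipeline for mapping disease-prone areas
    from case point locations and environmental criterion surfaces:
    semivariogram estimation and ordinary kriging of sparse station samples,
    global/local Moran's I and Getis-Ord hot-spot diagnostics,
    frequency-ratio class weighting of criteria, a seeded random-forest
    classifier over presence/pseudo-absence points, Jenks natural-breaks
    risk classing, and ROC/RMSE/MAE plus leave-one-factor-out AUC-drop
    sensitivity validation. Includes a synthetic-data generator (Gaussian
    random fields, inhomogeneous point processes) so the whole pipeline is
    testable with known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
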