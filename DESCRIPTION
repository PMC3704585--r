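Package: kdpanel
Title: Spatio-Temporal Ecological Regression for Kawasaki Disease Surveillance Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for ecological analysis of age-stratified disease
    surveillance panels, built around the epidemiology of Kawasaki disease
    and its link to the total fertility rate. Provides crude and
    demography-adjusted incidence and mean patient age from age-class case
    and population panels, Box-Cox normalization with profile-likelihood
    estimation of the power, maximum-likelihood spatial-lag regression on a
    binary adjacency matrix, random-effect AR(1) panel regression with a
    lag/smoothing grid search over distributed-lag covariates, retrograde
    reconstruction of national series from fitted models, and a synthetic
    surveillance-panel generator with known ground truth based on a
    catalytic force-of-infection model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
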