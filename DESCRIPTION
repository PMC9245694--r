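Package: lakehybrid
Title: Hybrid Empirical Dynamic and Two-Box Oxygen Modelling for Deep Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing and forecasting deep-water dissolved oxygen in
    large monomictic lakes by coupling empirical dynamic modelling (simplex
    projection, S-map locally weighted regression, convergent cross-mapping,
    and state-dependent interaction tracking) with a parametric two-box
    oxygen/physics model. Includes a climate/nutrient scenario engine that
    computes a hypoxia management benchmark, seeded synthetic-lake generators
    with known causal structure and analytic Jacobians for validation, and a
    command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
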