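Package: ricestor
Title: Pesticide Residue Kinetics, Forecasting and Quality Grading for Stored Rice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pesticide residue dynamics in rice during
    storage under controlled temperature and relative humidity. Simulates
    residue dissipation series with bi-exponential decay and a unimodal
    temperature/humidity response, forecasts next-step residues with a
    learning-to-rotate attention sequence model trained from scratch, grades
    grain quality by K-means clustering of a paired measured/predicted residue
    index with silhouette-based selection of the number of grades, and
    provides first-order kinetic fits with half-lives, Duncan's multiple range
    test with compact letter display, and quadratic response-surface fits on
    coded factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
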