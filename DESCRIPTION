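Package: pathclock
Title: Interpretable Pathway-Guided Neural Network Age Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds transcriptomic age clocks as knowledge-primed artificial
    neural networks whose connectivity is constrained by gene-set annotation:
    genes feed only the hidden neurons of the pathways they belong to, each
    pathway is condensed into a single linear "pathway age" neuron trained
    with an auxiliary loss, and a stacked ensemble averages independently
    trained members into the final age prediction. On top of the fitted clock
    the package provides in silico perturbation (single-gene knockdown and
    overexpression, dose-response curves, genome-wide knockdown scans, and
    complex differential-expression signature perturbations), pathway-level
    statistics (age-correlation ranking against a random-gene control pathway,
    age-stratified effect tests with Holm adjustment, crossroads association,
    and a tSNE pathway landscape), and a synthetic-data generator with planted
    pathway-structured age effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp,
    Rtsne
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
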