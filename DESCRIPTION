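Package: curricula
Title: Curriculum Learning Theory for Sparse Teacher-Student Perceptrons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical theory and matched simulators for curriculum learning
    in high-dimensional teacher-student perceptrons with a sparse teacher.
    Provides exact order-parameter dynamics for online stochastic gradient
    descent with closed-form generalisation metrics, a replica-symmetric
    saddle-point solver for batch ridge-regularised logistic learning with an
    elastic Gaussian coupling between sequential training phases, finite-size
    stochastic and convex-optimisation simulators used as empirical oracles,
    and experiment drivers that map where curriculum, anti-curriculum, or
    shuffled example ordering wins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
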