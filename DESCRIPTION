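Package: tbnsens
Title: Mutational Sensitivity of Threshold Boolean Networks via Ergodic Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how the long-term dynamics of threshold
    Boolean models of gene regulatory networks respond to the loss of
    single regulatory interactions. Provides synchronous threshold
    dynamics and exhaustive attractor enumeration, construction of
    Ergodic Sets (terminal strongly connected sets of attractors under
    single-gene expression flips), stationary distributions of the
    flip-induced Markov chain with an optional penalty on flips that
    oppose active regulation, an edge-deletion sensitivity score based
    on the total-variation distance between wild-type and mutant
    Ergodic Set occupancies together with a four-way decomposition of
    the displaced probability mass, adaptive-walk in-silico evolution
    towards maximally sensitive or maximally robust networks, and
    batch ensemble experiments with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
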