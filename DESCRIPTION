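Package: hyperfix
Title: Fixation Dynamics of Birth-Death Processes on Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying constant-selection evolutionary dynamics on
    hypergraphs, where a reproducing node converts all co-members of one of
    its hyperedges (model 1) or does so only when its type holds a strict
    majority in the hyperedge (model 2). Provides generators for complete,
    cyclic and star 3-uniform hypergraph families, symmetry-reduced Markov
    chains with banded and sparse absorption solvers, printed closed-form
    fixation probabilities for small families, an exact brute-force solver
    over all 2^N type configurations, a compiled stochastic simulator with
    Wilson confidence intervals, one-mode projections, degree- and
    size-preserving randomization, and classification of a structure as an
    amplifier or suppressor of selection against the Moran-process baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
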