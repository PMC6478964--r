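Package: evograph
Title: Exact Fixation Probability and Time on Evolutionary Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolutionary graph theory on undirected, unweighted
    graphs. Computes exact fixation probabilities and mean conditional
    fixation times of a single mutant under Moran Birth-death (and
    death-Birth) updating by solving the full 2^N-state absorbing Markov
    chain, enumerates all connected unlabeled graphs of small size with
    analytic cycle-index cross-checks, constructs extremal graph families
    (comet-kites, detours, generalized and coupled stars, l-graphs), runs a
    genetic algorithm over graph space to optimize fixation probability or
    time, and classifies graphs as amplifiers, suppressors or piecewise
    suppressors of selection. Includes graph6 input/output interoperable
    with standard graph-generation tools and a Monte Carlo simulator as an
    independent check of the exact solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
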