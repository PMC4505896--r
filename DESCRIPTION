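Package: TEpopdyn
Title: Population Dynamics and Transposition-Rate Inference for Transposable Elements
Version: 0.1.0
Authors@R:
    person("Anna", "Keller", email = "anna.keller@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of transposable element
    (TE) copy-number evolution in diploid populations under
    transposition-selection balance, with fecundity selection, a
    recombination map and pool-style sampling of the final generation.
    Includes a simulation-ensemble maximum-likelihood test for
    transposition-rate heterogeneity between two species, the
    copy-number and insertion-frequency statistics used in comparative
    TE surveys, interval algebra for refining repeat annotations
    (microsatellite filtering, same-family merge/link chaining,
    cross-family overlap resolution, orthologous-block linking), and a
    synthetic-data module that generates every input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
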