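Package: trackcoloc
Title: Index-Based Colocalization Analysis of Genome Tracks with a
    Complete Permutation Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies colocalization between two genome tracks
    (stretch-stretch or stretch-point) using normalized indices of
    overlapping, asymmetry and coverage defined on nearest-neighbor
    pairs. Statistical significance is assessed with a complete
    permutation test over all K(K-1)/2 length swaps, summarized by a
    zeta statistic whose significance thresholds are calibrated by
    Monte-Carlo simulation of random tracks and mapped onto Gaussian
    p-values. Includes per-chromosome and genome-wide reporting with
    binomial aggregation, a randomness assessment for center
    positioning used to select the permutation scheme, and a
    simulation harness for false-discovery-rate validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
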