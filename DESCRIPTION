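Package: dominet
Title: Minimum Dominating Set Analysis of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes exact minimum dominating sets (MDSets) of undirected
    protein interaction networks by branch-and-bound on the standard binary
    integer program, stratifies proteins into essential, MDSet and essential
    MDSet (e-MDSet) sets, and provides the accompanying network statistics:
    degree-threshold enrichment curves under label-resampling nulls,
    betweenness bottleneck enrichment, degree-ordered deletion robustness
    trajectories, protein complex participation coefficients with
    intra/inter-complex interaction enrichment under size-preserving
    complex reassignment, and COG-style functional class enrichment under
    label-permutation nulls. Includes a seeded generator of synthetic
    studies (scale-free networks with planted essentiality, complexes and
    functional classes) and a one-call pipeline producing a machine-readable
    analysis report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
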