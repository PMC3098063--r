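Package: rsdlite
Title: Reciprocal Smallest Distance Ortholog Detection with a Local
    Two-Phase Map-Style Executor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-contained implementation of the reciprocal smallest
    distance (RSD) algorithm for detecting orthologous protein pairs
    between two genomes.  Replaces the external tools the classical
    pipeline shells out to with internal components: an affine-gap
    Smith-Waterman search with Karlin-Altschul E-values, a
    Needleman-Wunsch global aligner with an alignable-fraction filter,
    and a maximum-likelihood pairwise amino-acid distance estimator
    under empirical rate matrices with discrete-gamma rate
    heterogeneity.  Includes a local map-style two-phase executor
    (runner files, part files, retries, worker blacklisting, a
    persistent result store), a workload and cost planner for
    all-against-all genome comparisons, and a sequence-evolution
    simulator that generates genome pairs with known ortholog and
    paralog structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    phangorn,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
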