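Package: castalign
Title: Fast Three-Stage Protein Structure Alignment and Similarity Search
    on C-Alpha Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rigid-body alignment of protein backbones reduced to their
    C-alpha traces, in three stages: gapless local alignments are seeded by
    comparing intra-molecular distance matrices; each seed is grown into a
    rigid-body superposition by iterated least-squares fitting over a
    conflict-tolerant set of candidate residue pairs; and the candidate set
    is finished into a conflict-free correspondence either sequentially
    (dynamic programming over diagonal runs, order-preserving) or
    non-sequentially (maximum-cardinality bipartite matching).  Alignments
    are scored with the Q-score and SAS_k match measures.  The package also
    provides a classification-based structure-search engine (greedy
    complete-linkage grouping at a Q-score threshold, representative-first
    two-phase query), synthetic backbone generators (ideal alpha-helices,
    self-avoiding coils, noisy rigid copies, chimeras) that make every stage
    testable without external downloads, PDB input/output, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
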