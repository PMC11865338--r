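Package: bhwa
Title: Multi-Rank Weighted Microbiota Disturbance Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the Bio-taxonomic Hierarchy Weighted Aggregation
    (BHWA) approach to comparing entities (dietary fibers, diseases) by
    the microbiota disturbances they induce. Evidence of directional
    microbial abundance change is propagated up a six-rank taxonomy,
    quantified with an inverse-document-frequency weighted signed count,
    compared by cosine similarity per taxonomic rank, and aggregated
    across ranks with inverse-deviation weights into a single weighted
    similarity with a t-based p-value and Benjamini-Hochberg FDR control.
    Includes signed network construction, three-node-loop coherency
    statistics with a permutation null, body-site-specific disturbance
    scores, complete linkage clustering with Newick export, and a
    synthetic evidence generator with planted block structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
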