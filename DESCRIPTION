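Package: dollosa
Title: Tumor Phylogeny Inference from Single-Cell Mutation Matrices
    under a Dollo-k Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of cancer progression trees from
    noisy ternary single-cell genotype matrices under a restricted Dollo
    model of evolution: every mutation is gained exactly once, lost at most
    k times, with at most d losses in the whole tree.  The error model
    supports mutation-specific false-negative (allelic dropout) rates, a
    global false-positive rate and missing entries; the tree space is
    searched by simulated annealing over four neighbourhood operations
    (subtree prune-and-reattach, add/remove a deletion, label swap).  Also
    provides a synthetic-data generator with Beta-distributed dropout rates
    and Triangular loss priors, accuracy metrics for tree comparison
    (ancestor-descendant and different-lineage accuracy, flip parsimony,
    three-gamete conflict counting), display-only tree collapsing by node
    support, and Graphviz DOT output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
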