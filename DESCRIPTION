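Package: rnaet
Title: Evolutionary Trace Ranking and Structural Cluster Analysis for RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the columns of an RNA multiple sequence alignment by
    phylogenetic importance using the Evolutionary Trace method (integer ET
    and the entropy-weighted real-value ET), quantifies the spatial
    clustering of top-ranked nucleotides in tertiary, secondary, or primary
    structural context with analytic z-scores, measures their overlap with
    annotated functional sites under a hypergeometric null, and optimizes
    input-alignment selection over random sub-alignment ensembles using
    clustering z-scores, rank entropy, and ET smoothness. Includes a
    synthetic-fixture generator producing tree-structured alignments with
    planted functional sites and toy helix structures, so every pipeline
    stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
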