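Package: hlanet
Title: Network Analysis and Neighbor-Edge Prediction of HLA-Peptide Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted bipartite networks from qualitative Class I
    HLA-peptide binding records, identifies binding modules by fast greedy
    modularity optimization with a weight-permutation null model,
    characterizes peptides and HLA pseudo-sequences per module, and predicts
    edge labels with Nebula, a two-sided neighbor-edge collaborative filter
    thresholded at the unbiased leverage. Includes leave-one-out and repeated
    k-fold cross-validation drivers with rank-based ROC/AUC, and a synthetic
    planted-module data generator for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
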