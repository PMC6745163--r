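Package: tsnets
Title: Tissue-Specific RNA Co-Expression Networks from Multi-Tissue
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores the tissue specificity of miRNAs, lncRNAs and mRNAs
    across a multi-tissue, multi-sample expression matrix using the Gini
    index of the per-tissue median expression vector, classifies each RNA
    as tissue-specific, nonspecific or intermediate, assigns each
    tissue-specific RNA to its maximal-expression tissue, and builds
    per-tissue cross-biotype Pearson co-expression networks at a
    configurable absolute-correlation threshold. Includes a synthetic
    expression generator with planted housekeeping and tissue-specific
    RNAs and latent-factor co-expression for end-to-end recovery testing,
    plus readers and writers for TSV/GCT matrices, edge lists and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
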