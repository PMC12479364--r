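Package: tfhsig
Title: Consensus Differential-Expression Signatures for Follicular Helper T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives core, regulatory (T_FR) and pathogen-specific T follicular
    helper (T_FH) cell transcriptional signatures from multi-condition bulk
    RNA-seq by consensus rules over fold-change-thresholded moderated-t
    differential expression, and projects those signatures onto bulk,
    pseudobulked single-cell and spatial expression data by bounded rank-based
    single-sample scoring. Includes the full supporting pipeline: TMM
    normalization, precision-weighted linear modelling with empirical-Bayes
    moderation, TREAT-style fold-change-threshold tests, preranked gene-set
    enrichment with a permutation null, kNN-Jaccard Louvain clustering with
    pseudobulk differential expression, CLR normalization for antibody-tag
    counts, and a synthetic-data module that generates bulk, single-cell and
    spatial datasets with known planted signature structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
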