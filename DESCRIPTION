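Package: mitodemux
Title: Demultiplexing Pooled Single-Cell Libraries Using Mitochondrial
    Germline Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns cell barcodes in pooled single-cell genomic libraries
    (mtscATAC-seq, ASAP-seq, DOGMA-seq, full-length scRNA-seq) back to their
    donor of origin and detects cross-genotype doublets using only
    mitochondrial germline variants.  Provides a barcode-aware mitochondrial
    pileup and SNV caller with VarScan-style thresholds, per-cell
    reference/alternative allele count matrices, K-means/GMM genotype
    clustering with sample-specific germline variant selection, a
    beta-binomial posterior doublet model with KNN rescue, silhouette-based
    estimation of the number of pooled donors, a synthetic pooled-library
    simulator with ground-truth doublets, and evaluation metrics (accuracy,
    ARI, AUC, TPR/FDR, concordance tables).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    mclust,
    cluster,
    class,
    clue,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
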