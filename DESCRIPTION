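Package: cohesintools
Title: Quantitative Analysis of Intragenic Cohesin Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterizing stimulus-dependent changes in
    cohesin (Rad21) binding inside gene bodies. Provides MA-based
    normalization of two-condition ChIP-seq peak intensities, extraction of
    decreased intragenic cohesin sites (DICs) within transcriptionally
    responsive genes, low/high-CTCF subtype classification, Hi-C
    contact-matrix metrics (distal-to-local ratio, inter-chromosomal
    fraction, insulation score, aggregate peak analysis), chromatin-loop
    anchor statistics, and a machine-learning layer (k-means clustering,
    SMOTE-balanced logistic classification with chromosome-held-out
    evaluation, elastic-net feature selection). A synthetic-data generator
    with planted ground truth makes every stage testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
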