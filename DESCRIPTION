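Package: gagam
Title: Genomic-Annotated Gene Activity Matrices from Single-Cell ATAC-seq
Version: 1.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds gene activity matrices from single-cell ATAC-seq peak
    accessibility by functionally labeling peaks against a genomic model
    (gene bodies, exons, transcription start sites, and ENCODE-style
    candidate cis-regulatory element tracks). Peaks are labeled as
    promoter, distal enhancer, exon, or empty; gene activity is the
    weighted sum of a binary promoter matrix, a promoter-enhancer
    co-accessibility matrix, and a distance-weighted exon matrix,
    followed by per-cell normalization. Includes clustering evaluation
    metrics (adjusted Rand index, adjusted mutual information, residual
    average Gini index), an LSI embedding and clustering front-end, a
    windowed-correlation co-accessibility estimator, and a synthetic-data
    generator with planted cell types for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
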