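Package: circheart
Title: De Novo Circular RNA Discovery, Read-Through Filtering and Sponge
    Screening for Heart RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of an anchor-based
    circular RNA discovery and analysis pipeline for bulk RNA-seq: back-splice
    junction calling from unmapped reads via unique 20-mer anchors and
    canonical splice signals, genomic-origin annotation of junctions,
    classification of two-gene (read-through) circRNAs versus homology
    artifacts by flank alignment, SRPBM/FPKM quantification with detection and
    high-confidence filters, negative-binomial exact-test differential
    expression, circRNA/host-gene correlation, miRNA seed-site sponge
    screening on circular sequences, and cross-study junction-set comparison.
    Includes a deterministic synthetic-data generator (toy genome, annotation,
    reads, miRNA panel) with complete truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
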