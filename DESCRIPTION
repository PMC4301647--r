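Package: endolife
Title: Carbon-Source Transcriptome Pipeline for Bacterial Endophytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of bacterial RNA-seq contrasting growth on
    two carbon sources: suffix-array read mapping with a unique-hit policy
    (exact and one-mismatch), CDS-containment read counting, RPKM and
    quantile normalization, a negative-binomial conditional exact test for
    differential expression with common-dispersion estimation, hierarchical
    clustering of condition profiles on Spearman correlation distance with
    length-aware functional-category enrichment, and projection of a
    reference regulatory network through an ortholog map with
    sign-consistency filtering and hub-regulator ranking. Includes a
    synthetic-data generator (genome, annotation, reads, design, regulon,
    orthologs) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
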