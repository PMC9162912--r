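Package: editscape
Title: Detection and Temporal Analysis of A-to-I RNA Editing from RNA-seq
Version: 0.1.0
Authors@R: person("editscape", "developers", role = c("aut", "cre"),
    email = "editscape@example.org")
Description: A reusable pipeline for genome-wide adenosine-to-inosine (A-to-I)
    RNA editing analysis from aligned RNA-seq reads. Implements high-confidence
    site calling through a pileup mismatch filter cascade (base/mapping quality,
    coverage, mismatch rate, known-SNP exclusion, cross-sample recurrence),
    editing-level quantification as G/(G+A), annotation of sites by genomic
    region, protein recoding consequence, repeat-element context and flanking
    sequence composition, k-means discovery of temporal co-editing patterns
    across ordered developmental stages, linear-model association of overall
    editing with ADAR enzyme expression, and cell-barcode pseudobulk editing
    quantification for droplet single-cell data. Ships a fully specified
    synthetic-data generator (reference, gene and repeat annotation, SNP
    confounders, planted editing trajectories, bulk and barcoded reads) with
    serialized ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
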