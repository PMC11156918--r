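Package: chondromap
Title: Chondrogenic Enhancer Landscape Analysis from Sorted-Population
    Chromatin Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls putative chondrogenic and non-chondrogenic enhancers from
    replicated ATAC-seq peaks and differential H3K27ac coverage between
    sorted (reporter-positive and reporter-negative) cell fractions of two
    tissues, classifies their tissue specificity, assigns them to
    topologically associating domains (TADs) and categorizes chondroTADs
    versus chondroEnhTADs, quantifies transcription-factor binding overlap
    against an inactive-chromatin control, attributes cumulative
    height-variance of GWAS loci to overlapping enhancer sets, and scores
    motif-hit enrichment against calibrated log-odds thresholds. Ships a
    deterministic synthetic-data generator with ground-truth labels for
    every stage so the whole pipeline is exercisable and testable without
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
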