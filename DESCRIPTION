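Package: pirnaquant
Title: Mappability-Aware Quantification of piRNA Cluster Expression
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying expression of uni-strand piRNA clusters
    such as Drosophila flamenco from stranded RNA-seq and small RNA-seq.
    Provides exact k-mer mappability tracks and interval mappability
    filtering, binned (1 kb non-overlapping and 100 kb sliding window)
    log2 fold-change analysis with the pseudo-count and discard rule
    variants used for somatic-cell and ovary libraries, a positional
    5'-to-3' gradient summary, a small RNA processing chain (adapter
    clipping, randomized-end trimming, contaminant removal, seeded
    multimapper assignment, read classification, miRNA-anchored
    normalisation), gene and transposon-level count matrices with
    transposon-proximity annotation of gene promoters, delta-delta-Ct
    qPCR quantification, and quantification of nuclear versus cytoplasmic
    RNA-FISH foci and perinuclear body particles in confocal images.
    A seeded synthetic-data generator (toy genome with engineered
    transposon repeats, stranded reads with positional decay, raw small
    RNA libraries, ground-truth microscopy images) and a minimal
    exact-match aligner make every step testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    EBImage,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
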