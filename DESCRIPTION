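Package: graftmobile
Title: Detection of Graft-Transmissible Mobile mRNAs in Plant Heterografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for identifying bidirectionally mobile mRNAs
    (mb-mRNAs) in plant heterografting systems from deep RNA-seq of grafted
    tissues. Reconstructs genotype-matched modified reference genomes from
    resequencing data (pileup variant calling with depth, zygosity and
    quality filters; variant incorporation with coordinate lift-over;
    de novo assembly of genotype-specific scaffolds), partitions RNA-seq
    reads of each graft library into resident and foreign fractions by
    cross-genome matching, and calls mobile transcripts with homograft
    false-positive subtraction, donor-expression filtering, an FPKM
    threshold and replicate intersection. Includes a synthetic grafting
    simulator with complete truth tables, and the small physiological
    calculations (relative electrical conductance, delta-delta-Ct
    expression ratios) used to validate mobile-transcript predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    methods,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
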