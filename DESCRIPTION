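Package: pirnakit
Title: Genic piRNA Cluster Profiling, Allele-Specific piRNA Accounting and
    H3K9me3 Enrichment Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for characterising gene-resident Piwi-interacting RNA
    (piRNA) clusters from small RNA sequencing data. Implements length and
    ncRNA-contaminant filtering of small-RNA libraries, an exhaustive
    desk-scale short-read aligner with best-stratum unique filtering and a
    perfect-match allele-specific mode on a merged diploid genome, ping-pong
    signature Z-scores and 1U/10A nucleotide biases, RPKM quantification,
    strand-resolved coverage and dual-strand cluster calling, pairwise locus
    structural comparison (SNPs, indels, transposon-insertion gaps), k-mer
    mappability tracks, ChIP-seq RPGC normalization with input subtraction
    and Mann-Whitney region enrichment comparison, and seeded synthetic-data
    generators with complete ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
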