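Package: bulkscan
Title: SNP-Index Bulked Segregant Analysis with Permutation Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq style bulked segregant analysis of biparental
    populations sequenced as phenotypically extreme pools. Computes per-bulk
    SNP indices from allele depths with parental homozygous-polymorphic marker
    selection, smooths the delta SNP index in sliding windows, derives a
    genome-wide significance threshold from the permutation distribution of
    the genome-wide maximum, calls candidate regions, annotates coding
    consequences of SNPs against gene models, and intersects region genes
    with differential-expression tables to produce a prioritized candidate
    list. Includes a recombinant-inbred-line pool-seq simulator (single-seed
    descent, Haldane map function, depth-limited pooled allele counts) that
    generates complete synthetic input bundles, plus nitrogen-use-efficiency
    phenotype utilities for extreme-bulk selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    e1071,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
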