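Package: readthroughr
Title: Quantify Stop-Codon Readthrough from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for genome-wide analysis of stop-codon
    readthrough from ribosome profiling data. Builds transcript-coordinate
    models from GFF3/FASTA annotations, assigns P-sites and reading frames to
    ribosome footprints, computes an edge-trimmed frame-0 readthrough
    efficiency statistic with expression filters and High/Low grouping,
    assembles a stop-codon-context feature set (mRNA channel nucleotides,
    nascent-peptide exit-tunnel properties, 3'-UTR descriptors, negative
    controls), fits cross-validated random-forest models with permutation
    feature importance, and runs nucleotide-context enrichment statistics
    (Wilcoxon median shifts, chi-square goodness-of-fit and independence
    residuals, Spearman correlations). Includes a fully seeded synthetic
    ribo-seq generator with known per-gene readthrough ground truth so every
    pipeline stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    randomForest,
    utils,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
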