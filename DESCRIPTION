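Package: methlink
Title: Integrated Differential Methylation and Expression Analysis for
    Knockout-Rescue Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Paired analysis of DNA methylation arrays and RNA-seq counts in
    knockout/rescue experiments. Simulates paired methylome-transcriptome
    datasets with known ground truth; normalizes counts by median-of-ratios
    and calls differential expression with a negative-binomial Wald test;
    filters and quantile-normalizes beta values, calls differentially
    methylated positions with a moderated t-test on M-values, and aggregates
    promoter and gene-body regions by Stouffer combination; classifies
    features as rescued by one or both re-expressed isoforms; links
    methylation positions to gene transcription start sites within a cis
    window, scores pairs by Spearman correlation with permutation-based
    false discovery rates, and labels pairs canonical (negative) or
    non-canonical (positive); intersects linked genes across species through
    an ortholog map and reports direction concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    S4Vectors,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    DESeq2,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
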