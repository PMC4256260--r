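Package: spliceindel
Title: Aberrant Splicing Detection from Isoform-Level Quantification and
    RIP Target Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects aberrant splicing from isoform-level RNA-Seq
    quantification (FPKM) across two conditions. Transcripts are
    classified as expressed or absent by replicate-mean FPKM thresholds,
    condition-unique isoforms are called with a one-sided Welch t-test,
    and each unique isoform is globally aligned (affine gaps) to its
    gene's standard form -- the isoform with the highest wild-type
    expression -- to call insertion and deletion splicing events with
    signed sizes, transcript-relative locations and 5'UTR/gene-body/3'UTR
    region labels. A companion module calls RIP-Seq enriched target
    transcripts (IP versus IgG), classifies their regulation against
    differential-expression results, and reports the overlap between
    aberrantly spliced genes and bound targets. A seeded synthetic-data
    generator produces ground-truthed transcriptomes, quantification and
    RIP tables for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
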