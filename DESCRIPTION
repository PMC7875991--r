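Package: isotail
Title: IsomiR Calling, 3' Tailing Statistics and Differential Expression
    for Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for microtranscriptome analysis of small
    RNA-seq data: adapter clipping, quality filtering and read collapsing;
    strict (exact, sense) mapping to pre-miRNA hairpins with a +/-2 nt
    templated window for miRNA quantification; lenient (up to two
    mismatches, all placements) mapping with decomposition of each read
    into templated 5'/3' offsets and nontemplated U/A tails (isomiRs);
    arm-resolved uridylation statistics and 13-17 nt fragment
    surveillance; a simplified negative-binomial Wald test with
    median-of-ratios normalization and Benjamini-Hochberg adjustment;
    log-odds position-weight-matrix scanning of promoter regions; and a
    fully ground-truthed small RNA read simulator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    Rcpp,
    generics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
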