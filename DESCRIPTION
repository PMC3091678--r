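Package: regulonscan
Title: Orthology-Aware Motif Scanning and Regulon Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts transcription-factor binding sites and regulons in
    bacterial genomes by scanning transcription-unit upstream regions with
    a position weight matrix whose columns are weighted by background-
    normalized information content, reinforcing candidate sites with the
    scores of matching sites upstream of orthologous genes in reference
    genomes (bidirectional-best-hit orthology), assessing significance
    against an empirical null of length-matched random coding sequences,
    summarizing genome-wide confidence with log-odds-ratio curves, and
    comparing predicted regulons across genomes through an ortholog-aware
    Jaccard similarity turned into a neighbor-joining conservation tree.
    Ships the 48 curated 14-bp cyanobacterial LexA boxes used to seed such
    scans, and a synthetic multi-genome generator with planted motifs for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
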