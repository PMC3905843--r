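Package: phqscan
Title: Strand-Resolved Scanning of Putative Hybrid G-Quadruplex Motifs
    Around Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans gene sequences for putative DNA:RNA hybrid
    G-quadruplex-forming sequences (PHQS), intramolecular G-quadruplex
    sequences (PQS) and isolated G3 tracts on both DNA strands using
    lazy-loop pattern semantics, bins hits into TSS-centred frequency
    distributions, masks regulatory motifs (interval and ordered literal
    masks) to measure their contribution, computes the non-template vs
    template strand-bias statistic over the 1 kb downstream window, and
    summarises per-gene motif prevalence and abundance. Includes a
    synthetic promoter simulator that plants motifs with known position,
    category and strand so every pipeline stage can be validated against
    exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
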