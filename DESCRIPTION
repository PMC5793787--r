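Package: spliceclouds
Title: Splicing Coordination from Droplet-Barcoded Linked Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-molecule splicing information from
    droplet-barcoded (linked-read) spliced alignments and tests for
    coordination between distant alternative splicing events on the same
    RNA molecule. Provides gene-model classification of pure exon-skipping
    events and terminal alternative splice sites from GTF annotation,
    junction-evidence extraction with anchor-length filtering, molecule
    calling with collision detection, percent-spliced-in and
    molecules-per-million quantification, Fisher's exact coordination tests
    with Benjamini-Yekutieli or Benjamini-Hochberg false discovery rate
    control, extent estimation across informative-count cutoffs with
    multivariate-hypergeometric down-sampling controls, and a
    droplet-encapsulation simulator with known truth for calibration.
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
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    rtracklayer,
    Rsamtools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
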