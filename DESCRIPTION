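Package: methdomains
Title: Whole-Genome Bisulfite Methylome Analysis and Domain Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) methylome
    analysis: strand-aware per-cytosine methylation calling from aligned
    bisulfite reads, bisulfite conversion-rate estimation from non-CpG
    positions, methylation-state classification and feature-level summaries
    (promoters, gene-body subregions, repeats), non-overlapping-window
    methylation tracks, segmentation of partially methylated domains (PMDs)
    and Dnmt3a-protected domains (DPDs), rank correlation of window tracks
    with external genomic signals, and association of deregulated genes with
    domain-level methylation loss. Includes a synthetic-methylome and
    bisulfite-read simulator with planted domain architecture so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    magrittr,
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
    yaml,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
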