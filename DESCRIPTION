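Package: satkit
Title: Satellite DNA Discovery and Quantification from Low-Coverage Shotgun Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for discovering and quantifying tandem
    satellite repeats from low-coverage single-end shotgun reads: graph-based
    read clustering, satellite classification from cluster-graph shape and
    tandem periodicity, circular consensus monomer reconstruction by k-mer
    frequency walking, monomer annotation (GC content, interstitial telomeric
    motifs, in-silico restriction ladders with methylation sensitivity),
    conversion between genome proportion and copies per 1C, slot-blot
    calibration, and pairwise monomer identity summaries with distance-matrix
    export. Includes a synthetic-data generator emulating 454-style genome
    skimming of genomes carrying tandem satellite arrays, dispersed repeats and
    single-copy background, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
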