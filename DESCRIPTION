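Package: tilescreen
Title: Tiled CRISPR Spacer Library Screens on Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dense spacer-library screens of lytic phages with
    type III-A CRISPR-Cas systems. Designs tiled spacer libraries over a
    phage genome (both strands, fixed stride) and emits cloning-ready
    oligos; extracts direct-repeat-flanked spacers from amplicon FASTQ
    reads into count tables; computes spacer frequencies, post-infection
    enrichment ratios and strand-resolved enrichment landscapes with
    region summaries; maps naively acquired spacers to per-nucleotide,
    RPM-normalized strand coverage; correlates target transcript
    expression with spacer enrichment; and quantifies sorted-well
    regrowth, time-to-threshold, fluorescence group differences and
    escaper-phage fractions. A seeded synthetic-data generator emulates
    the genome layout, amplicon reads, class-dependent selection,
    RNA-seq coverage, acquisition reads and well growth curves, so the
    whole pipeline runs and is tested end-to-end with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
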