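Package: intronforge
Title: Build Group I Intron Databases with Refined Boundaries and Homing
    Endonuclease Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for constructing tabular databases of group I
    introns from covariance-model search hits and GenBank annotations.
    Refines exon-intron boundaries by intersecting Infernal hits with
    annotated intron features and compound-location gaps, validates
    boundaries against the conserved initial U of the splicing core,
    extracts flanking exonic context, classifies introns into structural
    subtypes from per-subtype covariance-model scores, maps named
    secondary-structure elements from Stockholm alignments, and detects
    putative homing endonuclease genes by open-reading-frame scanning
    under all NCBI genetic codes followed by keyword matching on
    InterProScan and DELTA-BLAST domain-annotation reports. Includes a
    seeded synthetic-fixture generator so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
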