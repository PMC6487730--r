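Package: fusionscape
Title: Gene Fusion Landscape Analysis from Chimeric RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls gene fusion candidates from chimeric split-read
    alignments (STAR Chimeric.out.junction-style records) under anchor
    length, junction-read support, homologous-pair and mitochondrial
    filters; classifies cohort-level recurrence of fusions across
    discovery and validation samples of tumor and adjacent normal
    tissue; tests recurrence enrichment with Fisher's exact test;
    cross-references known-fusion databases; annotates breakpoints
    against exon, UTR and protein-domain features; and summarises the
    fusion landscape (fusion-type classes, inter/intra-chromosomal
    ratios, partner counts, library QC percentages, 2^-ddCt relative
    expression). Includes seeded synthetic-data generators that plant
    fusions and calibrated noise classes in chimeric-read and cohort
    call tables, so the whole pipeline is testable against known ground
    truth without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
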