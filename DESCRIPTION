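Package: crisprtrip
Title: Multiplexed Profiling of Cas9-Induced Mutations in Barcoded Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed CRISPR-Cas9 mutation profiling in
    barcoded reporter amplicons (CRISPR-on-TRIP designs). Parses unique
    molecular identifier (UID)-tagged amplicon reads, aligns them to wild-type
    references with a semi-global affine-gap aligner, classifies repair
    outcomes (wild-type, deletion, insertion, complex, knock-in), aggregates
    per-reporter outcome frequencies and size spectra, decomposes the
    determinants of mutation frequency by type-II eta-squared ANOVA, associates
    frequencies with genomic feature tracks, resolves 1-bp insertion-site
    ambiguity under blunt, staggered and combined Cas9 cleavage models, and
    enumerates double-strand-break end structures from hairpin-capture
    bisulfite sequencing. Includes a fully seed-controlled synthetic-data
    generator emulating the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
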