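Package: g4flank
Title: Flanking-Nucleotide Effects on G-Quadruplex Topology from CD and
    UV-Melting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how flanking nucleotides shift the folding
    topology of intramolecular G-quadruplexes. Designs loop-permutation
    oligonucleotide libraries with 5'/3' flanking variants, computes the
    circular-dichroism conformation index r = CD265/(|CD265| + CD290) and
    classifies parallel, hybrid and antiparallel topologies, extracts
    melting temperatures from UV-melting curves by first-derivative
    analysis, and runs the flanking-effect statistics (delta-r, group
    spread, topology proportions, paired t-tests). A seeded synthetic-data
    generator produces CD spectra as convex mixtures of topology basis
    spectra and two-state van't Hoff melting curves with known ground
    truth, so every pipeline stage is testable without measured data.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
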