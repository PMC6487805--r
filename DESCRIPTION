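Package: taxamark
Title: Taxon-Specific Mutation Discovery and Target Selection for LAMP
    Primer Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects taxon-specific (group-conserved, outgroup-absent)
    mutations in multi-species, multi-strain nucleotide alignments while
    excluding strain-specific polymorphisms, profiles their density with a
    fragment-based sliding-window average mutation index, and exports
    masked target sequences ready for specific primer design in
    loop-mediated isothermal amplification (LAMP) workflows. Reads Clustal
    alignments (including the dialect with cumulative residue counts) and
    aligned FASTA with structured headers encoding taxon, gene and strain
    identity; includes a seeded synthetic-alignment generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    generics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    zoo,
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
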