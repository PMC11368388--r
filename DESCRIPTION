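Package: phagesynteny
Title: Gene Conservation and Synteny Diagrams for Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative genomics of annotated bacteriophage
    genomes. Parses GenBank flat files into columnar feature tables, validates
    their completeness, runs all-vs-all gene-level homology search (built-in
    Needleman-Wunsch aligner or external BLAST+), reduces hits to one best
    match per query gene and subject genome, derives gene conservation and
    uniqueness statistics over a user-chosen genome subset, and renders
    stacked linear synteny diagrams in which genes are colour-coded by
    conservation level and cross-links between adjacent genomes are shaded by
    percent identity. Includes an Entrez downloader for NCBI nucleotide
    records and a seeded synthetic-genome generator with a known homology
    manifest for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    arrow,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
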