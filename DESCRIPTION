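Package: mitepop
Title: Population Analysis of MITE Insertion Polymorphisms from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale re-implementation of a Stowaway-like miniature
    inverted-repeat transposable element (MITE) insertional-polymorphism
    analysis for resequenced plant genomes. Provides a synthetic population
    simulator (TA target sites with duplicated TSDs, family-structured
    insertions, paired short reads with known truth), a structural TIR/TSD
    element miner with ORF and DD39D transposase-motif triage, a
    junction-read insertion caller with consensus trimming and unique flank
    mapping, presence/absence matrix population statistics (unique and
    parallel insertion sites, proliferation coefficients, Monte-Carlo
    chi-squared contingency analysis, Jaccard distances and principal
    coordinate analysis), genic-context classification against GFF3-style
    annotations, p-distance neighbour-joining phylogenetics with bootstrap
    support, and concordance summaries against PCR genotyping calls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    data.table,
    stats,
    stringi,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
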