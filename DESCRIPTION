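Package: beeRFLP
Title: In-Silico PCR-RFLP Typing of Honey Bee Subspecies from COX1 Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular identification of Apis mellifera subspecies
    from diagnostic SNPs in the COX1 Folmer region. Simulates PCR with
    degenerate and mutagenic (dCAPS) primers in which primer sequences
    overwrite the template at product ends, models restriction digestion over
    IUPAC-degenerate recognition sites with isoschizomer resolution, searches
    primer-by-enzyme space for allele-specific cleavage assays, classifies
    digestion patterns into subspecies calls via a decision matrix, and
    provides Kimura 2-parameter distances, neighbor-joining trees and
    bootstrap supports for barcode alignments. Includes a seeded generator of
    658-bp Folmer-like haplotype fixtures that reproduce the packaged assay
    patterns, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
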