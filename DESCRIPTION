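Package: lonibarcode
Title: DNA Barcode Evaluation for Flos Lonicerae Japonicae and Related Lonicera Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate ITS2 and psbA-trnH DNA barcodes for the
    authentication of Flos Lonicerae Japonicae (the flower bud of Lonicera
    japonica) against its closely related adulterant species. Generates
    synthetic sequence panels that reproduce the published haplotype
    structure of the study vouchers, computes Kimura 2-parameter distance
    matrices under pairwise deletion, summarises intra- and interspecific
    divergence with the six standard barcoding metrics, assesses the
    barcoding gap, performs leave-one-out best-hit (BLAST1-style) species
    assignment, and builds neighbor-joining trees with bootstrap support
    and monophyly tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
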