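Package: barcodesig
Title: Regex Molecular Signatures for DNA Barcode Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Position-specific scoring matrix (PSSM) analysis of DNA barcode
    loci (matK, rbcL) for species discrimination, discovery of discriminating
    nucleotide sites at genus and species level, assembly of ordered literal
    patterns with exact inter-pattern distances into regular-expression
    species signatures, QR-code serialization of signatures, and
    signature-based classification of query barcode sequences with
    recall/precision/F-measure evaluation. Includes a synthetic barcode
    dataset generator with planted diagnostic sites for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    png,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
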