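Package: xlsearch
Title: Identification of Chemically Cross-Linked Peptides from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A search engine for cross-linking mass spectrometry (XL-MS).
    Builds cross-link search spaces (single, mono-linked, loop-linked,
    dipeptide and higher-order products) from protein FASTA databases,
    identifies noncleavable and MS-cleavable cross-linked dipeptides in
    centroided MS/MS spectra using a binomial-tail dipeptide score with
    per-peptide partial scores, detects cleavable-linker signature doublets
    by a three-stage cascade (strict quadruplet, top-intensity, relaxed
    pair), refines MS1 isotope patterns of heavy precursors, and controls
    the false discovery rate of cross-link spectrum matches through a
    posterior-error-probability model with target-decoy accounting.
    Includes a seeded simulator producing FASTA databases, MGF spectra and
    3D peak fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
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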