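Package: mitodetect
Title: Sensitive Detection, Phasing and Limit-of-Detection Analysis of
    Low-Frequency Mitochondrial DNA Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting low-frequency single-nucleotide variants on
    the circular human mitochondrial genome from long-read amplicon consensus
    sequencing. Implements extended circular reference coordinates to avoid
    origin-spanning mapping bias, strict pileup-based variant calling (base
    quality and alternative-read-depth thresholds), classification and
    validation of de novo variants, read-backed allelic phasing against two
    known cell-line haplotypes, and limit-of-detection analysis over
    two-cell-line dilution series. Also provides closed-form quantitation of
    mtDNA purity and enrichment from qPCR quantification cycles, apparent
    heteroplasmy arising from nuclear insertions of mitochondrial origin
    (NUMTs), expected duplicate-read fractions, and copy-number detection
    models for digital PCR and single-base-extension mass spectrometry. A
    seeded simulator generates mixture amplicon reads with known ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
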