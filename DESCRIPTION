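Package: herbq
Title: Diagnostic SNP Screening and Pyrosequencing-Based Quantification
    of Adulterants in Herbal Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and weighs adulterant species in powdered mixtures of
    closely related medicinal plants. Screens aligned DNA barcodes (e.g. ITS,
    matK) for group- and species-diagnostic single nucleotide polymorphisms,
    exports flanking sequence for specificity checks, converts pyrosequencing
    allele frequencies into per-species weights via an external mass standard,
    fits and gates quantitative standard curves, computes assay-validation
    statistics (linearity, limit of detection, limit of quantification,
    repeatability, bias), and simulates noisy allele-frequency measurements so
    the whole workflow can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
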