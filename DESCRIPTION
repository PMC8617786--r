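Package: bivalvID
Title: DNA Metabarcoding Toolkit for Bivalve Species Identification in Seafood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of mussel (Mytilidae), scallop (Pectinidae) and
    oyster (Ostreidae) species in seafood by DNA metabarcoding of a 150 bp
    mitochondrial 16S rDNA barcode. Provides the published seven-primer
    triplex assay as a built-in model, IUPAC-aware in-silico PCR for building
    customized barcode reference databases with species-resolution groups, a
    seeded paired-end amplicon read simulator for DNA extract mixtures, and a
    re-implementation of the amplicon analysis workflow (read merging, primer
    trimming, dereplication, edit-distance classification) with per-sample
    reports of reads assigned per species.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
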