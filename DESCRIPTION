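Package: rdnavar
Title: Simulation and Multi-Method Detection of Intragenomic rDNA Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study intragenomic sequence heterogeneity of the
    ribosomal DNA (rDNA) repeat array, with a focus on the fungal ITS
    barcode region. The package simulates tandem rDNA arrays with known
    haplotype structure under three heterogeneity models (accumulated
    mutation, hybridization, foreign-element insertion), emulates three
    detection arms (PCR-cloning-Sanger sequencing, multi-run targeted
    amplicon sequencing, and whole-genome shotgun sequencing), calls
    nucleotide variants from read pileups with hard filters on depth,
    quality, quality-by-depth and Fisher strand bias, reconciles variant
    evidence across methods with singleton-artefact and two-method
    rescue rules, classifies cross-method conflicts, and computes
    p-distance matrices, neighbor-joining trees, haplotype counts and
    read-proportion-based rDNA copy-number estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
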