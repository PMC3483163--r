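Package: lcltox
Title: Heritability and Kinship-Corrected Expression Analysis of Drug
    Cytotoxicity in Pedigreed Lymphoblastoid Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for pedigree-based drug-cytotoxicity studies in
    lymphoblastoid cell lines. Computes recursive kinship coefficients and
    relatedness matrices from pedigree files, converts alamarBlue plate
    absorbances to percent viability, fits four-parameter logistic
    dose-response curves with IC threshold extraction and
    sensitivity-of-drug-response (SDR) slopes, estimates trait heritability by
    maximum-likelihood variance-component models with boundary
    likelihood-ratio tests, performs kinship-corrected per-probe
    differential-expression testing with Benjamini-Hochberg control, clusters
    bivariate fold changes by k-means with confidence ellipses, validates
    expression by the 2^-ddCt qPCR method, and ships a synthetic-data
    generator reproducing the study design so the whole pipeline runs with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
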