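Package: ssrnm
Title: Single-Step Genomic Reaction Norm Models for
    Genotype-by-Environment Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits single-step genomic reaction norm models (RNM) for the
    analysis of genotype-by-environment (G x E) interactions in livestock
    populations with partially genotyped pedigrees.  Contemporary-group
    effects are estimated by BLUE and standardized into a continuous
    environmental gradient; intercept and slope breeding values are then
    estimated by REML under a hybrid pedigree-genomic relationship matrix,
    with either homogeneous or exponentially heteroscedastic residual
    variance.  Includes gradient-dependent heritabilities and genetic
    correlations, breeding-value accuracy and re-ranking diagnostics,
    window-based single-step GWAS of intercept and slope effects, and a
    gene-dropping simulator that generates pedigrees, partially genotyped
    SNP data (autosomes plus X), and phenotypes under the reaction-norm
    covariance structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
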