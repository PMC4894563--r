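Package: gblupr
Title: Genomic Prediction with Mixed Models and Marker-Derived Kinship
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solves Henderson's mixed model equations with user-specified
    variance-covariance structures for multiple random effects, estimates
    variance components by restricted maximum likelihood using three
    algorithms (single-kernel spectral EMMA, direct average-information,
    and expectation-maximization), and builds additive (VanRaden),
    dominance (Su) and epistatic (Hadamard) genomic relationship matrices
    from marker data. Supports prediction of unrealized crosses from
    mid-parent breeding values, single-cross hybrid prediction with
    general and specific combining abilities using Kronecker-product
    kernels, k-fold cross-validation of predictive correlation, a
    single-marker mixed-model association scan with polygenic control,
    and simulation of marker and phenotype data with controlled genetic
    architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), vcfR, optparse, jsonlite, withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
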