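Package: nbvst
Title: Statistical Error Models and Regularized Negative Binomial
    Variance Stabilization for UMI Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for choosing and fitting statistical error models for
    UMI-based single-cell RNA-seq count matrices. Implements per-gene
    Poisson goodness-of-fit testing with a library-size offset via
    randomized quantile residuals, maximum-likelihood estimation of the
    negative binomial inverse overdispersion parameter theta under a
    library-size offset, kernel-regularized parameter smoothing (the v1
    free-slope and v2 fixed-slope procedures), Pearson residual
    computation with a minimum-variance clamp, residual-variance based
    variable gene selection, depth-corrected counts, and the synthetic
    count generators (negative binomial simulation, binomial thinning,
    depth-targeted downsampling, metacell pooling) used to validate the
    error models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, Normalization, Regression
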