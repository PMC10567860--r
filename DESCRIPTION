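Package: pfpmi
Title: Post-Mortem Interval Estimation from Pericardial-Fluid Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the post-mortem interval (PMI) from quantified
    1H NMR metabolite concentration tables of human pericardial fluid. Implements
    age-constrained partial least squares regression (oCPLS2) whose latent score
    components are exactly orthogonal to a confounder such as age, with repeated
    k-fold cross-validation, randomization (permutation) testing of R2 and Q2,
    VIP-guided stability selection over Binary Matrix Sampling subsamples with an
    exact Poisson-binomial relevance test, age-corrected univariate metabolite
    profiling, PCA outlier diagnostics (Hotelling T2 and Q-residual tests), a
    stratified training/test split procedure, and a synthetic cohort generator
    that emulates the statistical structure of post-mortem pericardial-fluid
    metabolomics data with exported ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
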