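Package: comdimr
Title: Multiblock ComDim Data Fusion for Untargeted Metabolomics and
    Lipidomics
Version: 0.1.0
Authors@R:
    person("comdimr", "developers", email = "comdimr@example.org",
           role = c("aut", "cre"))
Description: Preprocessing and unsupervised data fusion for multiblock
    untargeted metabolomics and lipidomics feature tables measured on a
    shared cohort of samples. Implements prevalence filtering, per-sample
    median normalization, seeded uniform imputation of censored (zero or
    missing) intensities, base-10 log transformation, External Parameter
    Orthogonalization (EPO) against a nuisance factor, autoscaling,
    Frobenius-norm block scaling, Common Components and Specific Weights
    Analysis (CCSWA, "ComDim") with per-block saliences and explained
    variation, per-block univariate screening (Wilcoxon rank-sum or Welch t
    with Benjamini-Hochberg FDR), row-normalized top-k heatmap matrices,
    Hotelling T-squared confidence ellipses for score plots, and a
    synthetic multiblock generator with ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
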