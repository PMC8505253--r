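Package: subtypr
Title: Deep Ensemble Clustering of Resting-State ALFF Maps into
    Neurobiological Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers latent patient subtypes from voxelwise resting-state
    ALFF (amplitude of low-frequency fluctuations) maps. Implements a
    mass-univariate general linear model screen with Gaussian random field or
    permutation cluster-level correction, a stacked autoencoder that compresses
    the selected voxels into a family of low-dimensional representations,
    complete-linkage hierarchical clustering of every representation with
    label-aligned majority consensus, and a Jaccard-style robustness index used
    to merge unstable clusters across repeated runs. Includes a synthetic
    cohort generator with planted frontal/posterior-imbalance subtypes, subtype
    validation statistics (voxelwise contrasts with Cohen's d, FDR-corrected
    factor-score tests, logistic score associations with Nagelkerke pseudo-R2),
    and a single-seed reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
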