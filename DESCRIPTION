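Package: surfdecode
Title: Simulation and Multivoxel Decoding of Visual Surface Properties in
    Block-Design fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates block-design BOLD fMRI experiments on visual surface
    properties (gloss, roughness and their matched controls) and re-runs the
    full multivoxel pattern analysis on the synthetic data: run-level
    quality control by global-signal variance, GLM contrast t-maps and voxel
    selection, z-scored block-averaged response patterns, leave-one-run-out
    linear support-vector decoding, permutation-based null calibration of
    group accuracy, and the accompanying group statistics (one-tailed
    Bonferroni t-tests, two-way repeated-measures ANOVA with Tukey HSD,
    Wilcoxon signed-rank, d-prime). Also provides the image statistics used
    to check stimulus matching (luminance, contrast, histogram skew and
    radial power-spectrum differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    knitr,
    png,
    RNifti,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
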