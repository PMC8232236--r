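Package: pdcnet
Title: Partial Directed Coherence Connectivity Pipelines for EEG Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Directed (effective) connectivity analysis for multichannel
    resting-state EEG based on multivariate autoregressive (MVAR) modelling and
    partial directed coherence (PDC). Provides a seeded synthetic-cohort
    generator with known ground-truth directed coupling over an eight-region
    default-mode-network montage, a preprocessing chain (common average
    reference, zero-phase FIR band-pass, artifact rejection, downsampling,
    epoch segmentation), per-epoch MVAR fitting with AIC order selection and
    stability checking, frequency-resolved PDC with band averaging into the
    canonical EEG bands, Welch absolute band power, and a group-level
    statistical layer (one-way ANOVA with eta squared, Tukey HSD, Bonferroni
    correction, Kolmogorov-Smirnov normality screening, and Pearson
    correlation of connectivity with anxiety-scale scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
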