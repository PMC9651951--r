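Package: timefields
Title: Hierarchical Bayesian Estimation of Hippocampal Time-Cell Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying temporal compression in populations of
    hippocampal time cells. Provides a spike-train simulator with known
    ground truth, maximum-likelihood time-cell screening with even/odd
    reliability checks, Kolmogorov-Smirnov selection of power-law bounds,
    hierarchical Bayesian mixture models of per-trial time fields (Gaussian
    and log-normal fields, trial-varying location or width, power-law,
    exponential and Weibull population laws) fitted by an adaptive
    Metropolis-within-Gibbs sampler, WAIC model comparison, and the
    population-level statistics (width and trial-variability regressions,
    Bayes factors, early/late splits, event-timing correlations) used to
    test whether time-field peaks tile a logarithmic time axis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    digest,
    generics,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
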