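Package: brainsbi
Title: Simulation-Based Inference for Whole-Brain Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates connectome-coupled neural mass models (Wilson-Cowan,
    Jansen-Rit, Stuart-Landau with conduction delays, two-dimensional
    Epileptor, Montbrio mean-field, and reduced Wong-Wang with the pDMF
    anatomical parameterization), maps neural activity to BOLD through the
    Balloon-Windkessel hemodynamic model, extracts low-dimensional summary
    features (spectral, statistical, temporal, and functional-connectivity
    based), and performs amortized likelihood-free Bayesian inference on model
    parameters by training conditional normalizing flows (masked
    autoregressive flows and neural spline flows) on simulated
    (parameter, feature) pairs. Includes posterior shrinkage, z-score,
    correlation, and active-subspace sensitivity diagnostics, synthetic
    connectome generators for fully in-silico studies, and scripted
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    patchwork,
    pracma,
    withr
Config/testthat/edition: 3
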