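Package: ordinalMR
Title: Mendelian Randomization for Ordered Categorical Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage Mendelian randomization when the exposure is an
    ordered categorical variable arising from a latent continuous trait
    cut at fixed thresholds. The first stage fits an ordered-probit
    (latent threshold) model of the exposure on genetic instruments by
    maximum likelihood, identifying the instrument effects up to the
    latent residual scale; the second stage regresses the outcome on the
    fitted genetic score, estimating the causal effect on that scale.
    Includes bootstrap confidence intervals (normal, basic, percentile)
    with a CI-derived p-value, heritability-based rescaling to the
    natural exposure scale, MR-Egger pleiotropy testing, per-variant
    association scans with greedy LD clumping for instrument selection,
    a structural-model simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    boot,
    vcfR
Config/testthat/edition: 3
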