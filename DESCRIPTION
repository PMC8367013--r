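Package: r2er
Title: Unbiased Estimation of Model-to-Neuron Correlation Under Trial Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fraction of variance a model explains in the
    expected (noise-free) tuning curve of a neuron from trial-averaged noisy
    responses. Provides the bias-corrected estimator r^2_ER built from
    noncentral chi-squared moment corrections, estimate-centered credible
    intervals (ECCI) computed by Metropolis-Hastings posterior sampling and a
    bracketing search, an unbiased signal-to-noise ratio (SNR) estimator with
    a noncentral-F power interpretation, reference implementations of prior
    noise-ceiling estimators for comparison, a sinusoidal-tuning simulation
    engine, and a command-line interface for CSV response matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
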