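Package: copulagc
Title: Copula-Based Granger Causality Between Spike Trains and Local Field Potentials
Version: 0.1.0
Authors@R: person("copulagc", "authors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint modeling of mixed discrete and continuous neural time
    series with a Gaussian copula: a Gaussian autoregressive marginal for the
    local field potential (LFP), a probit-Bernoulli marginal for the binned
    spike train, cross-lagged histories in both conditional means, and an
    instantaneous (same-bin) dependence parameter. Provides maximum-likelihood
    fitting, AIC model-order selection, directional Granger causality from
    nested fits with permutation inference, time-resolved sliding-window
    estimation with trial-bootstrap standard errors, baseline normalization
    and condition contrasts, spike-artifact injection and least-squares
    template removal, trial preprocessing (zero-phase low-pass filtering,
    downsampling, spike binning, trial alignment), a full generative
    simulator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
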