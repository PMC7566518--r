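Package: mift
Title: Multitaper Estimation of Mutual Information in Frequency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures frequency-domain coupling between pairs of trialized
    time series such as local field potentials. Provides discrete prolate
    spheroidal (Slepian) tapers, multitaper power spectra and magnitude-squared
    coherence, and a multitaper estimator of mutual information in frequency
    (MIF) built on k-nearest-neighbour differential entropy estimates of
    Fourier increment samples, with naive, pre-averaging and post-averaging
    taper-combination strategies. Includes random-sinusoid simulation models
    with analytic ground truth, Monte-Carlo benchmarks of estimator correlation
    and variance, and sliding-window statistics for relating coupling to task
    performance: permutation max-statistic significance thresholds, moving
    block bootstrap confidence intervals for Pearson correlations, and a
    Z-test for comparing dependent correlations. All information quantities
    are reported in nats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
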