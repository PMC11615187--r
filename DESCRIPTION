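Package: ncreann
Title: Nonlinear MVAR Directed Connectivity for Band-Limited Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of linear and nonlinear directed (Granger-style)
    connectivity between neural sources with a single-hidden-layer neural
    network fit to a nonlinear multivariate autoregressive (nMVAR) model,
    together with the surrounding analysis pipeline: Morlet time-frequency
    decomposition and band power of epoched sensor data, sensor-level
    cluster-based permutation tests, LCMV beamforming with neural activity
    index maps and DBSCAN source clustering, time-shifted surrogate
    significance testing, and paired group-level contrasts with
    brain-behavior correlation. A seeded synthetic-data module generates
    ground-truth nMVAR systems, band-limited two-condition sensor epochs,
    leadfield-projected sources and correlated behavioral scores for
    validating every stage against known truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
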