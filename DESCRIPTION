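Package: modmindy
Title: Modulated Neural-Mass Models from Nonstationary Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits biologically constrained recurrent neural-mass models in which
    an excitatory/inhibitory baseline connectivity matrix is element-wise scaled
    by regime-specific rank-1 modulation matrices. Latent population activity is
    tracked with an extended Kalman filter on random data windows and all model
    parameters, including the noise covariances, are learned by gradient descent
    (NADAM) through the filtering and free-simulation errors. Includes a full
    synthetic ground-truth generator (hidden-Markov regime switching, sparse
    plus low-rank connectivity, lead-field observation model), EDF/BDF readers
    and EEG preprocessing, and a validation suite covering truth-masked parameter
    recovery, noise sweeps, split-half reliability and modulation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
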