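Package: tgdecode
Title: Temporal-Generalization Decoding and SSVEP-BCI Simulation for M/EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for time-resolved multivariate decoding of multichannel
    neural time series (MEG/EEG): within- and cross-condition temporal
    generalization with l2-regularized logistic regression, one-sample
    sign-flip cluster-mass permutation inference, activation-pattern
    (Haufe) transformation of classifier weights and dSPM-style
    noise-normalized source mapping on a synthetic lead field, plus an
    online SSVEP brain-computer-interface decoding stack (spatio-spectral
    decomposition, GLM amplitude estimation, calibrated linear
    classification and a sequential decision rule). A synthetic-data
    module generates forward models, condition-structured epochs,
    probabilistic-feedback task sessions and amplitude-modulated SSVEP
    streams so that every stage is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
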