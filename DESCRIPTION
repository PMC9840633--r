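Package: dhsig
Title: Dendrographic Hologram Signatures from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("DH", "Maintainers", email = "maintainers@dhsig.org", role = c("aut", "cre"))
Description: Computes p-adic dendrogram signatures of multichannel resting
    EEG. One-second per-electrode windows ("events") are clustered with
    Ward linkage into binary dendrograms whose root-to-leaf paths are
    encoded as 2-adic integers; counting branches below ball-derived
    thresholds yields the personal universal dendrographic-hologram
    signature (PUDHS) and, over a time series of block dendrograms, the
    personal block signature (PBDHS) with a randomized AUC-maximizing
    parameter search. Includes EDF/CSV input with zero-phase filtering,
    ROC/AUC evaluation with a random-grouping null, spectral band-power
    baselines, a synthetic EEG cohort generator for self-contained
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
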