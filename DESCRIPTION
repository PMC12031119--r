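Package: radarvitals
Title: Multiple Range-Bin Selection for FMCW Radar Vital-Sign Monitoring
Version: 0.1.0
Authors@R: person("radarvitals", "maintainers", email = "maintainers@radarvitals.dev", role = c("aut", "cre"))
Description: Contactless breathing- and heart-rate estimation from
    frequency-modulated continuous-wave (FMCW) radar recordings in which the
    body is mapped onto multiple range bins. Implements persistence-homology
    based selection of every range bin carrying a breathing or heartbeat
    signal (sublevel-set and Vietoris-Rips filtrations on time-delay
    embeddings, DBSCAN on persistence diagrams), chirp-median denoising,
    sliding-window epoching with continuity merging, autocorrelation and
    wavelet-based vital-rate estimators, magnitude-based artifact metrics,
    and a labeled synthetic FMCW scene simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
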