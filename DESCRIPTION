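Package: alphastate
Title: Alpha-Band Brain State Dynamics from Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes multichannel resting-state EEG alpha-band (8-12 Hz)
    Hilbert envelopes into recurrent brain states with an explicit-duration
    hidden semi-Markov model (multivariate normal emissions, lognormal dwell
    times), extracts per-participant fractional occupancy and mean state
    duration, and relates these dynamics to hallucination-proneness
    questionnaire scores via backward-elimination linear regression with
    bias-corrected accelerated (BCa) bootstrap confidence intervals. Includes
    a synthetic-cohort generator with known ground-truth state dynamics so
    the full pipeline is testable without access to restricted EEG data, plus
    readers for BrainVision and EDF recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
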