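Package: comask
Title: Simulation and Analysis Pipeline for Comodulation Masking Release and
    Binaural Masking Level Difference Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to synthesize the stimuli, simulate the psychophysics, and
    analyse the electrophysiology and salience ratings of a combined
    comodulation masking release (CMR) / binaural masking level difference
    (BMLD) masking study. Includes calibrated narrowband and broadband
    masker synthesis with comodulated or uncorrelated envelopes, a
    one-up two-down three-alternative forced-choice adaptive staircase run
    against configurable logistic virtual listeners, an auditory evoked
    potential (AEP) processing chain (epoching, linear detrending,
    zero-phase low-pass filtering, artifact rejection, iterative
    inverse-noise-power weighted averaging, change-complex extraction and
    N1/P2 peak scanning), rank-based (Friedman) analysis of salience
    ratings, and seed-deterministic synthetic-data generators with ground
    truth for closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
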