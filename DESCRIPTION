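Package: bimodalsrt
Title: Speech Reception Threshold Modelling for Bimodal Cochlear-Implant Listeners
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates speech-in-noise experiments for bimodal listeners (a
    cochlear implant on one ear, a hearing aid on the other) and predicts
    speech reception thresholds (SRTs) with two complementary model chains:
    a machine-learning chain (spatial scene, beamformer, device simulation,
    acoustic and electric feature extraction, hidden-Markov-model recognizer,
    SRT from a train-by-test SNR recognition matrix) and a speech
    intelligibility index chain (phase-inversion signal separation,
    equalization-cancellation binaural stage, band SNRs, SII, iterative SRT
    search), plus an instrumental SNR benefit metric. Includes a synthetic
    matrix-sentence corpus generator, speech-shaped and babble noise,
    a parametric four-microphone head model, adaptive differential
    microphone and binaural MVDR beamformers, multiband compression with a
    CAMFIT-style prescription, an ACE n-of-m coding strategy, and a
    stochastic integrate-and-fire auditory-nerve population model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
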