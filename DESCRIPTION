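Package: sbpsnn
Title: Emotional EEG Decoding with Self-Backpropagation Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for decoding emotional state from
    multichannel EEG with a three-layer spiking neural network trained by
    local plasticity (short-term plasticity, spike-timing-dependent
    plasticity, homeostasis) and self-backpropagation credit assignment.
    Includes a synthetic EEG generator with class-conditional band-power
    effects and directed coupling, standard EEG preprocessing (Butterworth
    filtering, ICA artifact removal, average re-referencing, baseline
    correction, Morlet wavelet band power), threshold spike encoding onto a
    471-node spatial grid, electrode-subnetwork mining by contribution-ranked
    elimination, fusion-model clustering, multiple-kernel-learning band
    attribution, and directed spectral Granger connectivity.
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
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
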