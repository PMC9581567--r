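Package: chimeratrf
Title: Auditory Chimera Synthesis and Temporal Response Function Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissociating acoustic from speech-specific cortical
    envelope tracking. Implements multiband auditory chimera synthesis
    (exchanging the temporal envelope and temporal fine structure of two
    sounds across log-spaced cochlear frequency bands), stimulus feature
    extraction (broadband envelope, envelope recovery from temporal fine
    structure, log-Mel spectrogram, phoneme indicator matrices), forward
    and backward temporal response function (TRF) modeling with ridge
    regression and nested leave-one-out cross-validation, and inference
    via partial correlations, trial-shuffle permutation nulls, bootstrap
    correlations, and binomial chance-level thresholds. A synthetic-data
    module generates speech-like stimulus pairs, ground-truth response
    kernels, phoneme sequences, and simulated EEG so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
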