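Package: courttone
Title: Courtroom Speech Emotion Analysis with a Residual CNN-BiLSTM-Attention Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for studying how the vocal
    emotions of courtroom participants relate to a defendant's emotional state
    and logical clarity. Provides a seeded synthetic courtroom-audio generator
    with a planted emotion-influence structure, log-Mel spectrogram features
    with delta and delta-delta channels, a from-scratch residual convolutional
    network with bidirectional LSTM encoding and attention pooling for
    three-class speech emotion recognition (angry, neutral, fear),
    silence-based utterance segmentation with role metadata, three-annotator
    consensus labelling, and record-level contingency-table analysis with
    chi-square and odds-ratio statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
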