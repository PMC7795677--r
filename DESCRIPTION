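Package: emofuse
Title: Fine-Grained Valence-Arousal Recognition from Wearable
    Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance-level (2-second) classification of emotional valence
    and arousal from multi-channel wearable physiological recordings
    (e.g., electrodermal activity, blood volume pulse, pupil dilation).
    Signals are filtered, resampled to a common rate, min-max normalized
    per trial and segmented into fixed-length instances; a shallow
    two-layer convolutional autoencoder learns per-modality latent codes;
    regularized canonical correlation analysis fuses the two modalities
    per video stimulus; and a broad learning system (random feature nodes
    refined by a sparse autoencoder, tansig enhancement nodes, ridge
    pseudo-inverse output weights) classifies each instance. Includes
    subject-dependent and leave-one-subject-out evaluation protocols,
    ablation and parameter-sweep harnesses, and a synthetic multi-rate
    dataset generator with a planted stimulus-locked affect process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
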