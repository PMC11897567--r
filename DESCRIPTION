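Package: eegstt
Title: Spatial-Temporal Transformer Decoding of EEG Emotion Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for emotion decoding from multichannel EEG.
    Implements the full pipeline from raw recordings to per-subject
    classification metrics: band-limited synthetic EEG generation with
    planted per-class band-power signatures, preprocessing (resampling,
    mastoid re-referencing, zero-phase FIR band-pass filtering, amplitude
    artifact rejection), per-second differential-entropy band features with
    overlapping temporal windowing and train-set normalization, a dual
    spatial/temporal transformer classifier over channel and frame tokens
    trained with AdamW and an exponential learning-rate schedule, and a
    subject-dependent trial-prefix evaluation protocol reporting accuracy,
    macro-F1 and confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
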