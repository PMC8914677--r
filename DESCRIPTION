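Package: harformer
Title: Sequence-to-Sequence Transformer for Wearable-Sensor Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A self-attention encoder for per-timestep classification of
    windowed six-channel inertial signals (tri-axial accelerometer and
    gyroscope), as used in smartphone-based human activity recognition.
    Provides the windowed-signal data model with CSV input/output and
    stratified splitting, an activity-pair data-augmentation algorithm
    (window concatenation with every-second-step downsampling under a
    min-count pairing rule), the transformer encoder itself (built-in
    signal standardization, learned position embeddings, pre-norm
    multi-head self-attention blocks, per-timestep linear head) with a
    hand-written reverse-mode gradient engine, an Adam training loop with
    warmup-cosine learning-rate schedule, label smoothing and global
    gradient-norm clipping, evaluation reports (confusion matrix,
    class-wise precision/recall/F1), attention-heatmap and
    position-embedding interpretability outputs, and a seeded generator of
    synthetic inertial datasets so the full pipeline runs without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
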