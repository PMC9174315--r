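Package: wsimil
Title: Weakly Supervised Multiple-Instance Learning for Whole-Slide
    Histology Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Slide-level weakly supervised classification of pyramidal
    histology images. Tiles whole-slide images into non-overlapping
    512x512 patches at 5x/10x/20x/40x with background filtering,
    restricts bags to tumor-area patches via a pluggable segmenter,
    trains an attention-pooling multiple-instance network per
    magnification with five-checkpoint ensembling, aggregates scores
    up the checkpoint/magnification/slide/patient hierarchy, and
    evaluates with ROC/AUC and the DeLong test. Includes clinical
    tissue-limitation simulators (single slide, k slides, needle-core
    strips), interpretability tools (attention heatmaps, Grad-CAM,
    attention-ranked patch clustering), and a seeded synthetic-cohort
    generator with planted class-conditional tumor textures so the
    full pipeline is trainable and testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
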