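Package: hemafuse
Title: Fine-Grained Blood Cell Classification with Layer-Fused Vision
    Transformers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for fine-grained single-cell morphology classification
    of stained blood cell images. Implements a class-token-free Vision
    Transformer whose per-layer encoder outputs are fused through a
    Squeeze-and-Excitation gate, trained with a dynamic-margin sub-center
    ArcFace loss, optionally initialized by masked-autoencoder (MAE)
    self-supervised pre-training. Includes the full augmentation pipeline
    (bicubic resize, random enhancement, random erasing), warmup plus
    cosine-annealing AdamW training loops, per-class evaluation metrics,
    architecture accounting (parameters and multiply-accumulates), and a
    synthetic stained-cell image generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
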