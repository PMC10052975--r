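Package: ViTLV
Title: Left-Ventricle Detection in Cardiac MR Relaxometry with a Vision
    Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the left ventricle in multi-echo cardiac magnetic
    resonance relaxometry sequences (T2*/T2/T1 mapping) by regressing a
    bounding box with a Vision Transformer trained under a 1-DICE box
    loss. Provides a synthetic short-axis phantom generator with known
    epicardial/endocardial masks and mono-exponential tissue decay,
    ground-truth construction including equiangular AHA segmental T2*
    analysis, the transformer encoder (patch embedding, multi-head
    self-attention, MLP blocks) with hand-derived gradients and an Adam
    trainer, subject-grouped stratified k-fold splitting, shift
    augmentation, and the full detection metric suite (IoU, DICE,
    centre-point errors, correct identification rate) with per-slice
    aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    RNifti,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
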