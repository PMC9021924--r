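Package: flowergan
Title: Style-Based Generative Adversarial Synthesis and Detection
    Evaluation for Flower-Head Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesizing flower-head images under unstructured
    field conditions with a style-based generative adversarial network, and
    for evaluating object detectors on such imagery. Provides a non-linear
    mapping network with center-of-mass truncation and style mixing, a
    style-modulated synthesis network with per-layer noise injection and
    Res2Net multi-scale blocks, a Wasserstein critic trained with gradient
    penalty, path-length regularization with a self-calibrating scale
    constant, detection metrics (average precision at an IoU threshold,
    error and miss rates), and a seeded procedural generator of labeled
    flower scenes with controllable illumination, overlap and occlusion.
    All gradients are computed by a built-in reverse-mode automatic
    differentiation engine that supports differentiating through gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
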