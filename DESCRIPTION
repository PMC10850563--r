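Package: mitodica
Title: Two-Stage Mitotic Figure Detection with Dilated Contextual Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for mitotic figure detection in histopathology images
    built around a dilated contextual attention (DiCoA) operator: sparse
    self-attention over dilated k x k pixel neighborhoods of a feature map,
    producing a weighted feature map and a per-pixel attention score field.
    Provides a two-stage detection/classification cascade with confidence
    fusion, sliding-window tiling inference with border-window relocation and
    non-maximum suppression, center-adjusted crop classification with a
    dual-backbone feature-concatenation head, high-power-field (HPF) selection
    and mitotic counting in automated (GA) and interactive (GB) modes, the
    standard detection metrics (precision, recall, F1, accuracy, specificity)
    with MAPE/MAE threshold sweeps, and a seeded synthetic histology generator
    so the whole pipeline is testable without whole-slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
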