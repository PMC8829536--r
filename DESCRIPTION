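Package: dctdetect
Title: Dynamic Color Transform for Illumination-Robust Object Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for illumination-robust object detection in plant
    phenotyping imagery built around a dynamic color transform (DCT): a
    small network predicts a global linear gain/offset pair (alpha, beta)
    from each input image, which is applied identically to all three color
    channels before detection. Provides both regression-based and
    classification-based parameter heads, encoder backbones with trainable
    parameter accounting, a pluggable detector interface with a minimal
    dense grid detector, GIoU-based detection losses, a two-step training
    procedure (detector first, then the transform through the frozen
    detector), voting-based ensembling of detection sets with test-time
    augmentation, the Average Domain Accuracy evaluation metric, and a
    synthetic multi-domain scene generator for end-to-end experiments
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
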