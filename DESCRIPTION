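Package: erosbci
Title: Single-Trial Classification of Event-Related Optical Signals with
    Compact Spatiotemporal Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-trial decoding of event-related optical
    signals (EROS) recorded over motor cortex during lateralized manual
    responses. Provides a synthetic frequency-domain optical data
    generator with montage-quality structure, the fast-optical-signal
    pre-processing chain (phase unwrapping, pulse regression, band-pass
    filtering, baseline correction, channel quality control, voxel
    projection, max-abs scaling), a compact depthwise-separable
    convolutional network classifier with max-norm weight constraints and
    three subject-specific training paradigms (montage-specific,
    cross-montage, pre-train/fine-tune), evaluation utilities (AUROC,
    fold-based confidence intervals, above-chance tests, data-quality
    ANOVA), and DeepLIFT (Rescale rule) feature attribution with
    confidence-grouped spatiotemporal heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
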