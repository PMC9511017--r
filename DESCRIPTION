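Package: mosaicbench
Title: Mosaic Sensor Simulation and Demosaicing Fidelity Benchmarks for
    Fluorescence Image-Guided Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates six-channel (visible plus near-infrared) surgical
    scenes, samples them through RGB-IR and bioinspired stacked-photodiode
    mosaic sensor models, reconstructs full-resolution images with five
    channel-independent interpolating demosaicing routines (bilinear, one-
    and two-dimensional cubic polynomials and natural cubic splines), and
    scores reconstruction fidelity with per-channel absolute-error,
    structural-dissimilarity, and CIELAB color-difference statistics,
    together with quantile-function comparison and routine ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    farver
Config/testthat/edition: 3
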