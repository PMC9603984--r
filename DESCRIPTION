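Package: orgaswell
Title: Quantification of Organoid Swelling Assays and Medium-Throughput
    Fluid-Secretion Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying epithelial organoid swelling from
    time-lapse bounding-box detections: disk-area estimation, particle
    tracking across frames, per-organoid linear swell-rate fits with
    quality-control exclusions, robust median/IQR plate normalization and
    interquartile-range hit calling for pooled 384-well compound screens.
    Includes the conventional fluorescence area-under-the-curve readout,
    Ussing-chamber short-circuit current step analysis, halide-sensitive
    YFP quench-rate estimation, a synthetic-data generator with known
    ground truth for end-to-end validation, and a reproducible pipeline
    runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    clue,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
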