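Package: pedometry
Title: Step-Detection Algorithms and Gait-Regularity Benchmarking for
    Wearable Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating pedometer step-detection
    algorithms on tri-axial accelerometer recordings. Implements the three
    classic detector families (peak detection with periodicity, similarity
    and continuity gating; dynamic-threshold crossing with timing
    regulation; adaptive-window normalized autocorrelation), running count
    accuracy (RCA) and F1 evaluation with one-to-one temporal matching, a
    grid-search parameter tuning protocol, and a synthetic gait simulator
    that generates regular, semi-regular and unstructured walking with
    ground-truth step and shift annotations, so detector robustness to gait
    regularity can be benchmarked without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
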