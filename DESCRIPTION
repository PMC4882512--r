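Package: saltatrack
Title: Saltatory Organelle Transport Analysis for Time-Lapse Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of saltatory organelle transport along
    axon-like processes, as used to study microtubule-dependent peroxisome
    trafficking. Provides a ground-truth generator for run-and-pause motion,
    rendering of synthetic fluorescence movies, spot detection on
    maximum-intensity projections, optimal-assignment track linking,
    per-track saltatory motion metrics (mean speed, event detection,
    fast-mover and direction classification), population-level statistics
    (quantile contrasts with bootstrap inference, summary t tests,
    chi-square tables, mixed repeated-measures ANOVA), and per-cell
    cytoplasmic fluorescence quantification from multi-channel images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
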