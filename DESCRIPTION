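Package: fretscreen
Title: Fluorescence-Lifetime FRET Screening Analysis for RyR Modulator Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence-lifetime (FLT) FRET
    high-throughput screens against the ryanodine receptor (RyR) and their
    downstream validation assays. Fits mono-exponential decay waveforms to
    recover donor lifetimes, converts lifetimes to FRET efficiency, normalizes
    1536-well plates against DMSO controls, calls hits at a standard-deviation
    threshold with donor-only and unlabeled-intensity false-hit filters,
    aggregates reproducibility across screen runs, and computes assay quality
    metrics (Z-prime, Gaussian control-distribution fit, hit rate). Also fits
    Hill dose-response curves for IC50 extraction, solves 1:1 Ca-EGTA buffer
    equilibria for free calcium, and analyzes skinned-fiber t-system calcium
    traces: rhod-5N calibration, plateau steady states, tetracaine-referenced
    RyR leak, and electrically evoked calcium-transient amplitudes. A
    synthetic-data module generates every input the pipeline consumes so the
    full workflow is testable without instrument recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
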