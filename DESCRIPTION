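Package: kymoquant
Title: Kymograph-Based Quantitation of Retrograde Axonal Transport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying single-cargo axonal transport from
    live-cell fluorescence microscopy, built around the kymograph
    representation. Includes a stochastic run-pause-switch simulator of
    retrogradely biased cargo motion (quantum-dot-labelled BDNF style), a
    microscope-like movie renderer (Gaussian point-spread function, Poisson
    shot noise, multi-page TIFF output), calibrated kymograph construction,
    automated ridge detection and track linking, run/pause segmentation,
    angle-based direction classification with the standard retrograde /
    anterograde / stationary cut-offs, per-cargo transport metrics (moving
    velocity, average velocity, pause percentage), fluorescent puncta and
    soma size-distribution analysis (Otsu segmentation, calibrated areas,
    size-class frequency tables), and the accompanying group statistics
    (Student's t test, one-way ANOVA with Bonferroni post test,
    mean +/- SEM summaries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
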