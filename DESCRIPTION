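Package: kinrepro
Title: Reproducibility Analysis for Repeated Depth-Camera Body-Tracking Runs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how reproducible markerless body tracking is when the
    same recording is processed repeatedly. Provides a seeded generator of
    multi-run joint-trajectory data, detection of the exponential
    initialization transient with a half-life based frame-discard rule,
    per-joint spatiotemporal dispersion ellipsoids and their convex-hull
    volumes, run-pairwise Euclidean distance and bone-length stability
    metrics, steady-value-range segmentation with switch detection, and
    cross-machine comparison of run sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
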