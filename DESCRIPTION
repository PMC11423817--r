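Package: dcvmotility
Title: Kymograph Track Analysis for Dense-Core Vesicle Axonal Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies bidirectional axonal transport of dense-core vesicles
    from kymograph particle tracks. Reads tracer output (long CSV or
    KymoButler-style JSON), repairs duplicate timepoints, converts pixel/frame
    coordinates to physical units, splits each trajectory into anterograde,
    retrograde and stationary segments with a sliding-window rule, and
    aggregates segment velocities into per-strain summaries, track motility
    classes, displacement distributions and combined-origin ensembles.
    Velocity distributions are decomposed into one-dimensional Gaussian
    mixtures selected by AIC and compared across conditions with pairwise
    two-sample Kolmogorov-Smirnov tests. Stationary vesicle clusters are
    detected and moving-track interactions (pass-through, stop, shedding) are
    scored. A stochastic run-and-pause transport simulator generates
    ground-truthed synthetic tracks in the same input formats, with presets
    parameterized for wild-type and kinesin-1 mutant strains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
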