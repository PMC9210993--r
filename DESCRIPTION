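Package: topomapr
Title: Phase-Encoded Topological Mapping on Cortical Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of phase-encoded cortical mapping experiments
    (retinotopy, tonotopy, somatotopy) on triangular surface meshes.
    Provides Fourier-based per-vertex phase and significance statistics of
    periodic responses, combination of direction-reversed runs with
    hemodynamic-delay cancellation, cross-subject complex averaging with a
    bivariate F-ratio mask, nearest-neighbor surface smoothing with FWHM
    estimation, tangential phase-gradient fields, visual field sign
    computation and connected-component parcellation into labeled areas,
    FreeSurfer-dialect surface, annotation and color lookup table I/O, and
    a synthetic-cortex generator that supplies ground-truth maps, periodic
    responses with hemodynamic delay and autocorrelated noise, and
    multi-subject cohorts with map jitter for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
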