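Package: spinemorph
Title: Shape Metrics, Puncture Mechanics and Morphospace Analysis of Genital Spines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of puncture-tool morphology and performance for
    genital spines and similar biological puncture tools. Provides automated
    spine-shape metrics from 2D sagittal profiles and 3D meshes (tip angle, tip
    radius of curvature, structural curvature, volume, morphotype flags),
    puncture-event extraction from force-displacement compression traces and
    per-spine performance summaries (puncture angle range, lowest and average
    force), landmark-based geometric morphometrics (generalized Procrustes
    analysis, shape PCA, permutation Procrustes linear models, phylomorphospace),
    pairwise shape-performance regressions, and a synthetic-data module that
    generates spine geometries and compression traces with known ground truth so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
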