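Package: visurf
Title: Population Receptive Field and Connective Field Analysis on Synthetic Cortical Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a cortical sheet with labelled visual field maps and
    known ground-truth receptive-field parameters, forward-models BOLD
    responses to a drifting-bar retinotopy stimulus, and fits unilateral and
    mirrored-bilateral 2D-Gaussian population receptive fields (pRFs) as well
    as Gaussian connective fields (CFs) over geodesic cortical distance from
    V1, for both stimulus-driven and resting-state signals. Includes the full
    case-versus-controls statistics layer used in hemianopia case studies:
    variance-explained and eccentricity thresholding, early/late visual area
    grouping, eccentricity-binned median sizes with bootstrap confidence
    intervals, size-eccentricity trend fits and slope-difference tests,
    median-difference and paired-condition t-tests, relative frequency
    distributions, and isosensitivity-curve AUC model comparison with
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
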