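Package: vmatrobust
Title: Control-Point-Resolved Robustness Analysis of VMAT Plans Under
    Intrafraction Motion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates intrafraction patient motion during volumetric
    modulated arc therapy (VMAT) of single-target cranial lesions and
    quantifies its dosimetric consequences at the resolution of individual
    control points. Provides a synthetic spherical-phantom plan generator
    with a multileaf-collimator (MLC) aperture model and an analytic dose
    engine, time-evolved 3D rigid motion traces drawn from published
    displacement distributions, rigid per-control-point dose-shift
    reconstruction, supersampled dose-volume histogram (DVH) metrics
    (V_Rx, D99%, DVH area under the curve), per-control-point motion
    sensitivity statistics (mAUC, sAUC), and aperture-area subpopulation
    analyses (Pearson correlation with Fisher-z intervals, Welch t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
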