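Package: gradientspace
Title: Locating Brain States in a Macroscale Gradient Coordinate System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating task-evoked and experience-sampled brain
    states in a low-dimensional coordinate system whose axes are macroscale
    functional connectivity gradients. Implements probe-level principal
    component analysis of multidimensional experience sampling (mDES)
    ratings with varimax rotation and cross-dataset projection, parcel-level
    first-level GLMs with parametric thought regressors and fixed-effects
    run averaging, Spearman rank-correlation state-space coordinates with
    Yeo-7 network summaries, and an inferential layer of linear mixed models
    (REML, sum-to-zero coding, type-III tests with Satterthwaite degrees of
    freedom, estimated marginal means) with cluster bootstrap confidence
    intervals. A seeded synthetic-cohort generator provides event schedules,
    parcel time series, probe ratings and brain maps with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    car,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
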