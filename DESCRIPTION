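Package: pamorph
Title: Central Pulmonary Artery Morphometry from CT Pulmonary Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Morphometry of the central pulmonary arteries (main, right and
    left pulmonary artery) from contrast-enhanced CT pulmonary angiography:
    Hounsfield-window masking and seeded region growing, 3D thinning-based
    centerline extraction with spur pruning and spline smoothing,
    cross-sectional area profiles perpendicular to the centerline, volume
    integration and slab-MIP diameter measurement. Includes synthetic CT
    vessel phantoms with exact analytic ground truth, a synthetic two-group
    patient cohort generator, and the downstream statistical toolbox used in
    pulmonary hypertension studies (normality-gated group tests, correlation,
    ROC with Youden cutpoints, DeLong AUC comparison, decision curve
    analysis, and forward stepwise linear prediction of pulmonary artery
    pressures).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
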