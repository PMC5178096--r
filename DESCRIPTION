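Package: lamotion
Title: Left Atrial Strain, Radial Motion Decomposition and Cardiac Fat
    Quantification from Cine and Dixon MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies left atrial (LA) function from tracked endocardial
    contours of long-axis cine cardiovascular MRI: longitudinal strain,
    radial motion fraction, phasic strain rates for the reservoir, conduit
    and atrial-contraction phases, and the decomposition of radial motion
    into components directed towards and perpendicular to the mitral-valve
    centre. Also provides 2-point Dixon fat quantification (septal ROI fat
    fraction and K-means epicardial fat volume within a cardiac mask),
    ventricular and atrial volumetrics, normality-gated two-group cohort
    statistics with intraclass correlation, and synthetic cine/Dixon
    phantom generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
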