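Package: plaquemorph
Title: Morphometric, Spectroscopic and Mechanical Characterisation of
    Calcified Arterial Plaque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the combined characterisation of atherosclerotic
    plaque tissue from three complementary experimental modalities:
    grey-value segmentation and 3D morphometry of calcification
    inclusions in micro X-ray computed tomography volumes (connected
    components, isosurface surface area, sphericity, geometry
    classification, calcification volume fraction), baseline-corrected
    ATR-FTIR absorbance peak-area composition ratios (lipid:collagen and
    calcification:collagen), and uniaxial stress-stretch summarisation of
    force-displacement records (Cauchy stress, initial stiffness, peak
    strength, stiffness grouping).  Includes synthetic phantom generators
    with analytic ground truth for every stage, and study-report helpers
    that join and aggregate per-specimen results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
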