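Package: bonemorph
Title: Micro-CT Bone Morphometry, Densitometry and Whole-Bone Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An automated pipeline for ex vivo micro-computed-tomography
    analysis of rodent long bones. Implements staged morphological
    segmentation of the trabecular and cortical compartments (the
    "morphological escalator": Otsu binarisation, despeckling, periosteal
    shrink-wrap, pore-space XOR and a coarse-to-fine open/close sweep),
    3D morphometry (bone volume fraction, local-thickness based Tb.Th and
    Tb.Sp, connectivity density from the Euler characteristic, trabecular
    pattern factor, triangulated bone surface, cross-sectional areas,
    polar moment and eccentricity), two-point hydroxyapatite density
    calibration (vBMD/TMD), three-point-bend structural and beam-theory
    material properties, and the factorial ANOVA / targeted t-test
    statistics layer used in longitudinal disuse-osteoporosis studies.
    Ships a synthetic phantom and cohort generator with analytic ground
    truth so the whole chain is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    yaml,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
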