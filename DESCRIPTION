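Package: fetalsubcort
Title: Few-Shot Subcortical Segmentation of the Fetal Brain in 3D Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying few-shot segmentation of fetal subcortical
    structures (choroid plexus, lateral posterior ventricle horns, cavum septum
    pellucidum et vergae, cerebellum) in 3D ultrasound volumes. Provides a
    synthetic ultrasound phantom generator with gestational-age-dependent
    growth laws, diffeomorphic demons groupwise registration for per-week
    template construction and weak atlas-label propagation, k-medoids
    clustering of template shapes, a multi-label 3D U-Net trained with a
    combined Dice and cross-entropy loss under gestational-age-aware
    augmentation, segmentation evaluation (Dice overlap, 95th-percentile
    Hausdorff distance, relative volume differences), and volumetric
    growth-curve estimation with significance-gated quadratic terms and
    prediction intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
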