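Package: thyrotex
Title: Texture Features and Discriminant Classification for Thyroid B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative texture analysis of B-mode thyroid
    ultrasound in the context of chronic autoimmune (Hashimoto) thyroiditis.
    Implements three region-of-interest texture features (smoothness,
    noise-thresholded minimum brightness, and the percentage of 8x8 blocks in
    a quadtree decomposition), five Gaussian discriminant classifiers with
    sensitivity/specificity/accuracy evaluation over lobe and section
    groupings, mean-brightness thresholding and pruned decision-tree
    baselines, and a full ROI shift/resize/rotation robustness protocol.
    Includes a seeded synthetic speckle-texture cohort generator so the whole
    pipeline can be exercised without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
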