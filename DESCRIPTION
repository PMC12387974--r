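Package: woundlidar
Title: Wound Size, Depth and Tissue Composition from LiDAR-Style Depth Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale re-implementation of an AI-based wound assessment
    stack for hard-to-heal wounds. Provides a pinhole-camera depth-map
    geometry layer (back-projection, per-pixel metric footprint, total
    least-squares plane fitting, bilinear upsampling), a parametric
    in-vitro wound phantom simulator with analytic ray-cast LiDAR
    rendering and synthetic wound-photo generation, wound surface-area
    and depth estimation against a reconstructed healthy-skin reference
    plane (with a +/-3 mm resolution sentinel and negative depths for
    hypergranulation), a two-stage U-Net slough/necrosis segmentation
    pipeline trained on the synthetic generator, and the
    accuracy/precision/coefficient-of-variation agreement statistics
    used to evaluate such devices against digital planimetry and probe
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
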