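Package: aswi
Title: Iterative Adaptive-Support-Weight Stereo Matching for Endoscopic Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dense disparity estimation from rectified stereo pairs and
    sequences using a truncated colour-plus-gradient matching cost,
    guided-filter cost-volume aggregation (adaptive support weights),
    winner-takes-all selection with sub-pixel refinement, and a
    consistency-enforcing postprocessing chain (weighted median,
    left-right check, occlusion filling, glare rejection). For video,
    per-pixel disparity-range masks built from the previous frame's map
    restrict the search range frame to frame. Includes a deterministic
    synthetic stereo-scene generator with ground-truth disparity and
    occlusion masks, disparity-to-depth and point-cloud conversion, an
    optical-resolution calculator for small-aperture endoscope optics,
    evaluation metrics (MAE/RMSE, equal-weight per-keyframe averaging),
    and readers/writers for PNG/PPM images, PFM float maps, and PLY
    point clouds.
License: MIT
Encoding: UTF-8
Imports:
    png,
    yaml,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
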