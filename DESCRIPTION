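Package: pensight
Title: Static-Camera Preprocessing and Dual-Stream Fusion for Pig Pen
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for occlusion-aware pig detection from fixed cameras.
    Implements a one-time static-camera preprocessing phase (background
    plate differencing with Otsu thresholding to produce
    background-suppressed images, and depth-based facility masking), a
    dual-input Background Suppression Integration stem that fuses the raw
    and background-suppressed views through attention-style modulation
    and 3D convolution, a seeded synthetic pen-scene simulator with
    visibility-filtered ground truth, detection metrics (IoU, AP50, F1),
    a convolution FLOPs accountant, and a small CPU-trainable dense
    detector for end-to-end seen-vs-unseen environment experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
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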