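Package: capclear
Title: Weakly Supervised Cleanliness Scoring for Colon Capsule Endoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses bowel cleanliness in colon capsule endoscopy video
    segments from weak, patch-level supervision. Trains an image-to-mask
    occlusion segmenter from binary 64x64 patch labels via a patch-restricted
    cross-entropy ("patch loss"), converts masks to per-frame mucosa
    visibility inside the circular field of view, aggregates visibility into
    the four CC-Clear frame-count features, classifies 10-minute clips with a
    depth-limited random forest under leave-one-out cross-validation, and
    reports chance-corrected agreement (Cohen's kappa) between raters and
    models. Includes a synthetic phantom generator (frames, clips, simulated
    raters) with known ground truth so every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    pROC,
    png,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
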