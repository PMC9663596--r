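Package: voxcog
Title: Voxel-Wise Encoding and Decoding Models for Diverse Cognitive Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxel-wise modeling of multitask fMRI experiments:
    delay-expanded (finite impulse response) ridge-regression encoding models,
    weight-based representational similarity analysis, principal-component
    cognitive spaces with metadata-based interpretation, cognitive-transform-
    function decoding that generalizes to novel tasks (task score and
    one-vs-one metrics), sensorimotor-voxel exclusion, and voxel-to-voxel
    reconstruction of cortical activity. Includes a synthetic multi-region
    data generator with controllable representational geometry so the full
    pipeline can be exercised and validated without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    ape
Config/testthat/edition: 3
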