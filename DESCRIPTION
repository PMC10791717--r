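Package: pwatr
Title: Automated Photographic Wound Assessment Tool (PWAT) Scoring from Wound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated prediction of the Photographic Wound Assessment
    Tool (PWAT) score from a wound photograph and its binary wound-bed
    segmentation mask. Derives the peri-wound mask by morphological dilation
    minus erosion, extracts 54 interpretable features per image (RGB and HSV
    channel statistics, two erythema indices, and the 13 canonical Haralick
    texture features of the grey-level co-occurrence matrix, on the wound and
    peri-wound regions), and fits an L1-penalized linear regression of the
    clinical PWAT grade with robust (median/IQR) feature scaling, repeated
    shuffled stratified cross-validation, and coefficient-based feature
    ranking. Includes a synthetic wound-image generator so the whole pipeline
    is testable without clinical data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
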