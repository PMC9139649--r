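Package: frlf
Title: Fuzzy Rank Level Fusion of Classifier Confidence Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-level fusion of confidence scores from an ensemble of
    classifiers using fuzzy ranks derived from the complement of a Gaussian
    density, with penalised top-K aggregation and an argmin decision rule.
    Includes the classical sum, product and majority-voting combination rules,
    binary diagnostic metrics (accuracy, precision, sensitivity, specificity,
    F1), a preprocessing pipeline for DaTscan-style SPECT volumes (slice
    extraction, black-border cropping, resizing, intensity scaling, brightness
    augmentation, train/test splitting), and a synthetic confidence-score
    simulator so the whole fusion-and-evaluation workflow is testable without
    imaging data. A command-line front-end ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    RNifti,
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
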