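Package: octunet
Title: Lightweight U-Net Segmentation of the Epidermis in OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated epidermal segmentation in optical coherence tomography
    (OCT) B-scans of skin, aimed at actinic keratosis imaging where
    hyperkeratosis and hair shadowing complicate delineation of the dermal-
    epidermal junction. Provides a synthetic speckle-phantom generator with
    known epidermis masks, a compact encoder-decoder U-Net with training
    (Adam, early stopping, learning-rate reduction) implemented natively in
    R with compiled strip-blocked convolution kernels, a seven-metric
    evaluation suite (accuracy, precision, recall, Jaccard, Dice, mean
    absolute error, Hausdorff distance), per-column epidermal thickness
    quantification with Pearson and Bland-Altman agreement analysis, and a
    hyperparameter sweep over image size, batch size and epoch count with
    overfit diagnosis and model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
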