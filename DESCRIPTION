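Package: kromnet
Title: Knee Range-of-Motion Classification from Monocular Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated classification of knee range of motion (ROM) after
    total knee arthroplasty from single monocular photographs. Implements
    the full KROMNet pipeline: Otsu-binarized grayscale preprocessing, a
    compact convolutional network with dilated convolutions and
    squeeze-style channel attention trained with cross-entropy, and
    clinically thresholded four-class and six-class ROM outputs. Because
    patient photographs are private, the package ships a seeded synthetic
    limb-pose image generator (two capsule segments hinged at the knee
    with controlled nuisance variation) so the whole pipeline is testable
    end to end, plus evaluation reports (confusion matrices, macro
    precision/recall/F1, accuracy) and channel-attention map export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    withr,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
LinkingTo:
    Rcpp
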