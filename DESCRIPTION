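Package: sonodescribe
Title: Breast Ultrasound Nodule Description and BI-RADS Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computer-aided description pipeline for breast ultrasound
    nodules. Detects and standardizes regions of interest, extracts the six
    BI-RADS descriptors plus echogenic halo and tumor-type suggestivity with
    an attention-based multi-head convolutional network, assigns the BI-RADS
    malignancy category with an explainable multinomial logistic regression,
    fine-tunes results with BI-RADS rules, and renders natural-language
    reports. Includes a synthetic speckle-phantom generator with known
    ground truth, scale-invariant near-duplicate image detection for dataset
    cleaning, and the Cohen's kappa / classification metric suite used to
    score agreement with expert annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
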