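Package: kidneynext
Title: Grouped-Convolution Multi-Branch CNN for Renal CT Slice Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference implementation of KidneyNeXt, a compact convolutional
    network for multi-class classification of renal CT slices (normal, cyst,
    stone, benign and malignant tumours). Provides the architecture (patchify
    stem, four-branch grouped-convolution blocks, strided transitions, global
    average pooling head) with exact shape tracing and parameter accounting,
    class-foldered image loading with stratified train/validation/test
    splitting, the fine-tuning protocol (SGD with momentum, per-epoch
    shuffling, L2 regularisation), confusion-matrix based one-vs-rest
    metrics with macro averaging, one-vs-rest ROC/AUC, Grad-CAM saliency
    maps, and a seeded CT-like phantom generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
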