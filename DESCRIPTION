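Package: fusnetcnn
Title: Multipath Residual Channel-Attention Networks with Robust Huber
    Losses for Plant Leaf Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lightweight convolutional classifier for plant leaf disease
    images built from multipath residual groups with channel attention and
    sub-pixel (pixel shuffle) feature fusion, trained with a family of
    robust Huber-type losses. Includes median-filter and min-max
    preprocessing, exact parameter and FLOP accounting against a fixed
    complexity budget, macro-averaged multiclass evaluation metrics with
    one-vs-rest ROC/AUC, a seeded synthetic leaf-image generator emulating
    class-per-directory datasets, and desk-scale training, loss-comparison
    and ablation harnesses. Forward and backward passes are implemented in
    R with compiled im2col/col2im kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
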