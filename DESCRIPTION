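Package: terseg
Title: Total Error Rate Evaluation of Cell Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised evaluation of cell image segmentation algorithms
    against ground-truth masks using the size-weighted total error rate
    (TER). Implements per-cell misclassification error rates (average,
    weighted, and proportion variants) from false-negative and
    false-positive pixel counts, constrained nonparametric bootstrap
    standard errors and normal-approximation confidence intervals for the
    TER, a Monte-Carlo study of the variability of the bootstrap standard
    error, synchronized-resampling estimation of the correlation between
    two algorithms' TERs, and correlated two-sample Z tests for comparing
    algorithms with statistical confidence. Includes label-mask matching
    with many-to-many merging, a synthetic mask and pixel-count generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    png,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
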