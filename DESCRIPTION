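Package: pairwave
Title: Gene-Pair Biomarker Discovery via Wavelet Peak Detection and
    Genetic-Algorithm Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers diagnostic gene pairs from case/control expression
    profiles. Expression values are calibrated against the control group,
    differentially expressed genes are found with a moderated two-sample
    t-test, genes are grouped by Gaussian-mixture clustering of principal
    component scores, and ordered into tracks by cluster and co-expression
    network degree. A continuous wavelet transform of the smoothed
    adjacent-gene difference signal flags candidate gene pairs, a genetic
    algorithm selects pair subsets by cross-validated accuracy, and a small
    feedforward neural network classifies samples from within-sample
    pair-difference features, which are invariant to per-sample scaling.
    Includes a synthetic cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    stats,
    utils,
    withr
Suggests:
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
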