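Package: sleepcascade
Title: Cascaded SVM Sleep-Stage Classification from Single-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Five-class sleep staging (W, N1, N2, N3, R) from a single EEG
    channel scored in 30-second epochs. Epochs are denoised by db8 wavelet
    threshold shrinkage, decomposed by a 7-level wavelet packet transform
    into six characteristic waves (alpha, beta, theta, delta, spindle,
    sawtooth), and summarised by a 51-feature system spanning time-domain,
    energy, frequency-domain and nonlinear-dynamics features (Lempel-Ziv
    complexity, sample, fuzzy, multi-scale, spectral and Renyi entropy).
    Features are ranked by the mutual-information quotient (MIQ) form of
    minimum-redundancy maximum-relevance selection and classified by a
    cascaded pair of one-vs-one quadratic-kernel support vector machines
    with class rebalancing for stage N1. Includes a minimal EDF
    reader/writer, a stage-conditioned synthetic EEG generator, holdout
    evaluation with confusion-matrix metrics, and TOPSIS scoring of
    feature subsets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
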