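Package: epistage
Title: Complexity-Based Graph Convolutional Staging of Epileptic EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for staging epileptic EEG recordings into normal, acute and
    chronic phases from nonlinear complexity features. Multichannel recordings
    are segmented into one-second epochs, band-limited to the fast-ripple band
    (250-500 Hz) with a Haar wavelet decomposition, and summarised per channel
    by five complexity measures (approximate, sample, permutation and fuzzy
    entropy, and Lempel-Ziv/Kolmogorov complexity). Per-epoch feature matrices
    are assembled into complete-graph samples and classified with a small
    Chebyshev graph convolutional network. Includes a statistical comparison
    layer (one-way ANOVA, Tukey HSD, principal component scores), an evaluation
    module (confusion matrix, accuracy, per-class F1), a synthetic
    stage-labelled EEG generator for end-to-end testing, and EDF/CSV input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
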