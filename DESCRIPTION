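Package: mtsimage
Title: Multivariate Time Series Classification via Gramian Angular and
    Markov Transition Field Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes multivariate time series as two-dimensional colored
    images and classifies them with convolutional neural networks. Each
    univariate channel is rescaled to [0,1], length-normalized by piecewise
    aggregate approximation (or linear interpolation), and encoded as a
    Gramian Angular Summation Field (GASF), Gramian Angular Difference
    Field (GADF), or Markov Transition Field (MTF). Per-channel images are
    rendered through a rainbow colormap, split into monochrome planes, and
    vertically concatenated into a single RGB image that feeds a small
    ConvNet or a VGG16-style network. An experiment harness runs repeated
    stratified k-fold cross-validation over encoder, concatenation-order
    and architecture conditions, and compares them with Dunn post-hoc,
    Wilcoxon signed-rank and Kruskal-Wallis tests. A seeded synthetic
    generator produces wafer-sensor-like fixtures (smooth baselines, level
    shifts, transient spikes) with controllable class separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
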