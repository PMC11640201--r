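Package: spiralpd
Title: Tremor Analysis and Parkinson's Disease Screening from Hand-Drawn
    Archimedean Spirals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts raster images of pencil-and-paper Archimedean spiral
    drawings into a tremor-deviation signal and classifies drawings as
    healthy or Parkinsonian. The pipeline binarizes the drawing with
    Gaussian-weighted adaptive thresholding, reduces it to a one-pixel
    skeleton with Zhang-Suen morphological thinning, unwraps the spiral into
    an angle-distance trace about its centroid, fits a smoothing-spline line
    of best fit whose residuals form the tremor signal, and summarises the
    normalized single-sided FFT spectrum of that signal with five frequency
    features (peak magnitude, peak frequency, signal-to-noise ratio,
    variance and bandwidth above a noise threshold). Two pencil features
    (stroke thickness and pressure) are extracted from grayscale intensity.
    A seeded synthetic spiral simulator with controllable tremor amplitude
    and frequency provides ground truth for testing, and grid-searched
    classifiers (decision tree, random forest, SVM, XGBoost, AdaBoost) with
    fold-wise normalization evaluate healthy-versus-Parkinson separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    rpart,
    ranger,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
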