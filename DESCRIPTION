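Package: tonguecolor
Title: Color-Space Feature Extraction and Classification for Tongue Image Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements an automated tongue-image classification pipeline for
    Traditional Chinese Medicine ZHENG differentiation. Extracts a 25-component
    per-pixel feature vector spanning eight color spaces (RGB, HSV, YIQ, Y'CbCr,
    XYZ, CIE L*a*b*, CIE Luv, CMYK), aggregates features over the entire tongue
    or its middle region with five statistical variants, trains AdaBoost, SVM
    (SMO with polynomial kernel) and multilayer-perceptron classifiers, scores
    them with weighted F-measure under stratified 3-fold cross-validation, and
    ranks/selects features by information gain and best-first search. Includes
    a synthetic tongue-cohort generator so the full protocol is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
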