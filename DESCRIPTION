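Package: seedxray
Title: Seed Viability Classification from X-ray Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A machine-vision pipeline for classifying seed viability from 2D
    X-ray projection images. Provides a synthetic radiograph generator that
    emulates viable (uniformly filled endosperm) and nonviable or abnormal
    (internal air spaces, irregular endosperm) seed morphology; Otsu-based
    seed masking and a three-stage intensity-enhancement chain; six texture
    feature families (basic intensity, local binary patterns, Gabor filter
    bank, basic contrast, Haralick co-occurrence statistics, and local
    Fourier features) at fixed per-family dimensionalities; Fisher-score
    ranked sequential forward selection; linear and quadratic discriminant
    and k-nearest-neighbour classifiers under stratified 10-fold
    cross-validation; six-way geometric augmentation with leakage-safe
    train/validation/test splitting; and a small from-scratch convolutional
    network baseline. A command-line driver ties the stages into a
    reproducible workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    class,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
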