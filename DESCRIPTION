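Package: wingbeatr
Title: Simulation, Detection and Classification of Insect Wingbeat Signals
    from Multi-Channel Optical Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with multi-channel (co-/de-polarized,
    dual-wavelength) optical backscatter recordings of flying insects:
    a synthetic wingbeat-signal generator with known ground truth,
    event segmentation by signal-to-noise thresholding with binary
    erosion and dilation, zero-padded Fourier featurization into
    harmonic and polarization-ratio features and a fixed-length
    spectral vector, three one-vs-all classifiers (dominant wingbeat
    frequency, Random Forest on scalar features, and a three-layer
    neural network on the spectral vector), and a bootstrapped
    one-vs-all evaluation protocol with pairwise accuracy matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    arrow,
    Rcpp,
    ggplot2,
    jsonlite,
    ranger,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
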