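Package: ripenet
Title: Residual Networks and Gradient Saliency for Hyperspectral Fruit
    Maturity and Soluble Solids Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing strawberry ripeness and soluble solids
    content (SSC, degrees Brix) from visible/near-infrared hyperspectral
    reflectance cubes.  Provides a synthetic hyperspectral phantom
    generator with pigment-driven endmember spectra and class-conditional
    SSC distributions; standard chemometric preprocessing (reflectance
    calibration, band cropping, Savitzky-Golay smoothing, pixel-wise area
    normalization, fruit segmentation, mean-spectrum extraction, spatial
    resizing); sample partitioning by stratified resampling, PLS-based
    outlier screening and SPXY maximin selection; one- and
    three-dimensional bottleneck residual convolutional networks for
    four-class maturity grading and SSC regression, trained by Adam with
    manual backpropagation; and gradient saliency attribution giving
    per-wavelength contribution profiles and per-pixel maps, extended to
    regression through a prediction-error-rate sample-selection rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    mixOmics,
    multcomp,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
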