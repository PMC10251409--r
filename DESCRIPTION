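Package: phospec
Title: Hyperspectral Estimation of Rice Leaf Phosphorus Concentration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating leaf phosphorus concentration (LPC) of
    rice from full-range (350-2500 nm) leaf reflectance spectra. Provides
    exhaustive two-band spectral-index optimization (ratio, difference and
    normalized-difference indices scanned over all band pairs), continuous
    wavelet-transform feature extraction with the Mexican Hat and related
    mother wavelets over ten dyadic scales, and a regression harness
    comparing partial least squares, LASSO, random forest, support vector
    and neural-network models over four input-variable sets, with 10-fold
    cross-validation, AIC scoring and Taylor-diagram statistics. Includes a
    synthetic leaf-spectra generator that emulates the phosphorus response
    of greenhouse-grown rice for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    randomForest,
    e1071,
    nnet,
    mixOmics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
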