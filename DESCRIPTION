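Package: photospec
Title: Photosynthetic Capacity from Leaf Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links leaf-level hyperspectral reflectance (350-2500 nm) to the
    biochemical determinants of photosynthetic capacity, the maximum RuBP
    carboxylation rate (Vcmax) and maximum electron transport rate (Jmax).
    Provides Farquhar-von Caemmerer-Berry A/Ci curve fitting with quality
    control and standard errors, chemometric spectral preprocessing (standard
    normal variate, Savitzky-Golay second derivative, autoscaling), univariate
    NIPALS partial least squares regression with RMSEP-based component
    selection and Selectivity-Ratio wavelength importance, a suite of
    published vegetation indices, and three validation designs of increasing
    rigor (leave-one-out, repeated random splits, and a water-stress date
    holdout). A synthetic-study generator emulating a mid-summer dry-down on
    a small tree population makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
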