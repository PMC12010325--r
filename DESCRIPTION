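Package: preedge
Title: Metal K-Edge Pre-Edge Difference-Spectrum Analysis and Model Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-energy-resolution fluorescence-detected
    (HERFD) metal K-edge pre-edge spectra, built around the discrimination of
    candidate structural models of the Mn4CaO5 oxygen-evolving complex by
    treated-minus-native difference spectra. Provides spectrum containers and
    manipulations (resampling, boxcar binning, trapezoidal area normalization,
    Gaussian/Lorentzian/pseudo-Voigt broadening of calculated stick spectra),
    experimental preprocessing (flash-population deconvolution, polynomial-spline
    rising-edge background removal, three-component Voigt peak fitting), a global
    energy-shift/intensity-scale calibration of calculated onto experimental
    spectra, RMSD-based ranking of candidate models with a pre-edge
    intensity-excess exclusion screen, and a fully seeded synthetic-data
    generator for end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
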