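Package: cpch
Title: Correlated Photon-Counting Histograms for Fluorescence Fluctuation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Resolves fluorescent species jointly by molecular brightness and
    diffusion using correlated photon-counting histograms (cPCH): the joint
    distribution of photon counts in two detection bins separated by a lag
    time. Provides closed-form factorial cumulants for 3D Gaussian
    observation volumes, three routes to the full count distribution
    (series, FFT of generating functions, recursion), moments-of-moments
    error estimates, the classical FCS/PCH/FCA limits as special cases, a
    raster-image (spatial) extension with flow terms, an analytic
    two-species inversion, a nested-sampling fitter, and Brownian-dynamics
    photon-emission simulators for point and raster-scanned acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
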