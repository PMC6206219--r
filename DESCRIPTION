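Package: thickpen
Title: Thick Pen Transform and Multi-Scale Association of Spectral Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale comparison of curves measured on possibly
    non-equispaced grids via the thick pen transform (TPT) and the thick
    pen measure of association (TPMA). The TPT redraws a curve with square
    pens of increasing thickness, yielding nested lower/upper boundary
    bands; the TPMA quantifies, scale by scale and point by point, the
    overlap of the pen bands of two or more normalized curves, taking
    values in (-1, 1]. The package applies the method to spectral
    irradiance measured in forest understoreys: it ships a synthetic
    generator of solar-like spectra with a factorial design (date, stand,
    sunlight position), a screening/averaging/comparison pipeline with
    summary statistics (curve maxima, PAR, red to far-red ratio), CSV
    input/output, plotting, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
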