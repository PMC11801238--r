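Package: aromadec
Title: Virtual Decoupling and Calibrated Uncertainties for Aromatic 13C-1H
    Protein NMR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enhancing the resolution of aromatic 13C-1H correlation
    spectra of uniformly 13C-labelled proteins. Provides a physics-based
    simulator of complementary two-dimensional time-domain dataset pairs
    (with and without a short 13C-13C coupling evolution delay) together with
    their virtually decoupled high-resolution targets; a three-part
    uncertainty-aware training objective that calibrates point-wise standard
    deviations by matching fractional moments of the standardized residuals
    to those of a unit Gaussian; a configurable spectrum-to-spectrum network
    with hand-derived gradients and an ADAM training loop; a two-state
    Bloch-McConnell longitudinal (ZZ/EXSY) exchange model with weighted
    least-squares fitting of exchange rates and populations; and reading,
    writing and processing of NMRPipe-format planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
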