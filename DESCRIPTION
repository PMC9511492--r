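Package: vsfgorient
Title: Orientation Analysis of Self-Assembled Sheets from
    Polarization-Resolved VSFG Microscopy
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Recovers the tilt angle of C7-symmetric supramolecular
    subunits in self-assembled sheets from polarization-resolved
    vibrational sum-frequency generation (VSFG) hyperspectral images.
    Provides the symmetry-reduced hyperpolarizability tensor and its
    Euler rotation into the eight measurable lab-frame susceptibilities,
    Voigt multipeak fitting of homodyne spectra, a synthetic-data
    generator for sheets and training sets, a feed-forward neural-network
    inverse solver with susceptibility sign enumeration under a two-sheet
    in-plane rotation constraint, spectral-class image segmentation, and
    independent geometric consistency checks on the recovered tilt.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
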