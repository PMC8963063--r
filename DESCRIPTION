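Package: ihtplan
Title: Fast Electro-Quasistatic Treatment Planning for Capacitive
    Interstitial Hyperthermia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-based electro-quasistatic (EQS) field solver and
    planning toolkit for dual-electrode capacitive interstitial
    hyperthermia applicators operating at 27 MHz. Provides an
    analytically equivalent simplified cuboid applicator model
    (capacitance-preserving adapted permittivity), per-electrode field
    superposition for fast re-evaluation of excitation settings,
    specific absorption rate (SAR) computation, Pennes bioheat transient
    solves with clinical temperature-constraint reports, benchmark
    phantom generators, and 3D gamma-index agreement analysis between
    SAR volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
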