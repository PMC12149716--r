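Package: smallfieldOF
Title: Small-Field Output Factors and Detector Output Correction Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for small-field radiotherapy dosimetry following the
    TRS-483 formalism: determination of detector field output correction
    factors (kQclin,Qmsr) and field output factors (Omega) from corrected
    detector readings.  Includes the analytical volume-averaging and
    positioning-uncertainty convolution over detector sensitive volumes,
    Birks-law ionization quenching for plastic scintillators, polarity and
    dose-per-pulse ion-recombination corrections, penumbra-based field-size
    and centering determination (11-points technique), bounded nonlinear
    curve fits of reading ratios and correction factors versus equivalent
    square field size, and quadrature plus two-level Monte-Carlo resampling
    uncertainty budgets.  A synthetic-data generator produces dose profiles,
    measurement sessions and secondary-electron spectra with known ground
    truth for end-to-end recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
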