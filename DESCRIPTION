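Package: NMRcoffee
Title: Quantitative 1H NMR Screening of Coffee for Quality and Authenticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative proton NMR screening of coffee extracts in
    deuterated chloroform. Implements 1D spectral processing (exponential
    apodization, Fourier transform, automatic phase and baseline correction),
    Lorentzian line-fit integration of analyte windows, PULCON-style
    quantification via an eretic factor for caffeine, 16-O-methylcafestol,
    kahweol, furfuryl alcohol and 5-hydroxymethylfurfural, method validation
    statistics (DIN 32645 detection and determination limits, linearity,
    recovery, precision, factorial ANOVA robustness), and authenticity
    screening rules for arabica/robusta discrimination and decaffeination
    compliance. A spectrum simulator with known ground truth stands in for the
    spectrometer so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
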