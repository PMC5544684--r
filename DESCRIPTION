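Package: opsinspec
Title: Spectral Analysis of Bistable Visual Pigments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing bistable photopigments from absorbance
    spectroscopy. Generates visual-pigment template (nomogram) curves
    parameterized by the wavelength of maximal absorbance, fits the
    long-wavelength flank of photoconversion difference spectra to estimate
    the metarhodopsin state and reconstructs the dark state additively,
    decomposes broad absorption bands into one or two template components
    with data-driven model selection, forward-simulates photosteady-state
    irradiation protocols as a synthetic-data generator, quantifies retinal
    isomer composition from HPLC chromatograms by Gaussian peak integration,
    and estimates G-protein activation rates from nucleotide-exchange time
    courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
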