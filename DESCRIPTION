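Package: dpvkit
Title: Differential Pulse Voltammetry Deconvolution and Flavin-Cytochrome
    Binding Analysis for Microbial Electrochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for whole-cell differential pulse voltammetry
    (DPV) and chronoamperometry of electrode-respiring bacteria. Provides a
    closed-form Nernstian forward model of the DPV response of reversible
    n-electron redox couples, charging-current baseline estimation and
    subtraction, multi-peak deconvolution by weighted orthogonal-distance
    regression, electron-count inference from peak half-widths, Langmuir
    binding analysis of flavin titrations (dissociation constants and site
    occupancy), and enhancement-factor analysis of flavin additions to
    microbial current-production traces across electrode potentials and pH.
    Includes a synthetic-data generator emulating voltammograms, titration
    series and current traces of Shewanella oneidensis MR-1 wild-type and
    outer-membrane cytochrome deletion strains, plus plain-text file formats
    for all record types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
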