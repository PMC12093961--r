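Package: ramanbleach
Title: Photobleaching-Based Unmixing of Single-Cell Raman and Autofluorescence Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous single-cell resonance Raman and
    autofluorescence microspectroscopy of pigmented bacteria. Time series of
    three consecutive exposures per cell are decomposed into a carotenoid
    resonance-Raman component and an autofluorescence component using
    photobleaching difference spectra and iterative polynomial (or arc-hull)
    baseline estimation. Downstream tools fit Lorentzian nu1/nu2 carotenoid
    peaks, compute silent-region signal-to-noise ratios and normalized
    intensities, classify autofluorescence spectral shapes by principal
    component analysis and X-means clustering with Bayesian information
    criterion splitting, and compare groups with the Kruskal-Wallis test
    followed by Dunn-Holland-Wolfe multiple comparisons and a compact letter
    display. A synthetic-spectra generator with known ground truth emulates the
    instrument for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
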