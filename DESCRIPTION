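Package: fluorpanel
Title: Optimal Fluorophore Panel Design for Fluorescence Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts per-detector signal and spectral bleed-through of
    fluorophores from excitation and emission spectra and the laser/bandpass
    layout of a measurement instrument, and designs optimal n-color
    fluorophore panels. Panels are ranked by a three-tier lexicographic
    criterion (detectors with bleed-through within a threshold, geometric
    mean of signals, mean bleed-through) and searched exhaustively or by
    multistart simulated annealing. Includes exact solution-space counting,
    prediction-versus-measurement agreement metrics, a synthetic
    Gaussian-spectrum fixture generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
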