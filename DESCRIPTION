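Package: txas
Title: Transient X-Ray Absorption Spectra: Synthesis, Band Kinetics and
    Hydrogen-Bond Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing femtosecond carbon K-edge transient X-ray
    absorption experiments on hydrogen-bonded systems such as aqueous urea.
    Synthesises core-to-valence absorption cross-sections from molecular
    trajectory transition tables (Lorentzian line shapes, ensemble averaging,
    Gaussian temporal instrument convolution, two-stage energy calibration,
    delta-OD construction), decomposes transient maps into a three-Gaussian
    band model with exponential amplitude kinetics, extracts sigmoidal
    half-rise and error-function 10-90 rise times, classifies geometric
    hydrogen bonds with proximal/distal donor assignment, and fits
    bi-exponential hydrogen-bond formation kinetics by maximum likelihood.
    Includes a seeded synthetic-data generator emulating proton-transferring
    trajectory ensembles and noisy pump-probe delta-OD maps so the whole
    chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
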