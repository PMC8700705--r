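Package: watercore
Title: Discrimination of Watercore Apples from Vis/NIR Full-Transmittance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying apples with the internal watercore disorder
    from visible/near-infrared full-transmittance spectra collected on an
    online grading line. Implements per-wavelength one-way ANOVA F-value
    scanning with characteristic-wavelength selection at local maxima,
    exhaustive two-band-ratio search with a scalar threshold discriminator,
    a least-squares support vector machine (RBF kernel) with grid-search and
    stratified 10-fold cross-validation, SPXY/Kennard-Stone calibration set
    partitioning, scan-block preprocessing (saturated-scan trimming,
    averaging, wavelength cropping), and a synthetic spectra generator that
    emulates the healthy/watercore class structure in three measurement
    orientations so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
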