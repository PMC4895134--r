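Package: skyspec
Title: Calibration, Colorimetry and Extended CIE Models for Sky Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of downwelling illumination across daylight, twilight
    and night. Implements a spectrometer calibration chain (dark-noise,
    wavelength and radiometric calibration with quality control),
    solar-elevation-indexed aggregation with lunar-phase filtering, CIE 1931
    colorimetry including the daylight locus and sRGB rendering,
    least-squares fitting of linear spectral basis models, and an iterative
    residual procedure that extends the CIE daylight model to
    location-specific six-component models of rural (airglow-dominated) and
    urban (sodium-lamp-dominated) night skies. Includes a seeded synthetic
    sky-spectrum campaign generator with a two-instrument acquisition model
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
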