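Package: filmcal
Title: Model-Based Calibration for Radiographic Film Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating radiographic film dosimetry systems with
    the single-target single-hit response model in pixel-value form. Fits
    calibration curves from as few as one to three dose points using
    universal background and saturation parameters, transfers calibration
    curves across irradiation geometries (field size, depth) via saturation
    and sensitivity-slope parameter ratios, inverts pixel values to dose,
    and quantifies dose uncertainty both analytically (error propagation at
    film-response midrange) and by Monte Carlo simulation. Includes a
    synthetic-data generator that emulates multi-field calibration film
    exposures, scanner readout noise, and day-to-day parameter variation,
    plus a command-line interface for fitting, curve derivation, dose
    inversion, and uncertainty reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
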