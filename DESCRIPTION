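Package: patlakGFR
Title: Single-Kidney Glomerular Filtration Rate from Dynamic
    Contrast-Enhanced MRI via the Rutland-Patlak Plot
Version: 0.1.0
Authors@R:
    person("patlakGFR", "Developers", email = "patlakgfr@example.org",
           role = c("aut", "cre"))
Description: Quantifies single-kidney glomerular filtration rate (GFR) from
    dynamic contrast-enhanced MRI bolus-track data. Provides serial-dilution
    calibration of signal intensity to gadolinium concentration (exponential
    model with AIC-based comparison against a cubic polynomial),
    baseline-subtraction and ROI curve extraction from dynamic series,
    Savitzky-Golay smoothing, partial-volume (residual-tissue) correction,
    bolus landmark detection (aortic first/second maxima, first minimum,
    renal peak, aorta-to-kidney delay), and a time-shift-modified
    Rutland-Patlak graphical fit converting the slope into per-kidney and
    total GFR normalized to body surface area. A synthetic-data generator
    (arterial input function with recirculation, two-compartment kidney
    curves, measurement noise, rendered dynamic series) replaces in-vivo
    scans for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
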