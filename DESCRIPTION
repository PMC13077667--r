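Package: epidqa
Title: EPID-Based Linac Quality Assurance Analyses with a Synthetic Portal-Image Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses for electronic portal imaging device (EPID) based linear
    accelerator quality assurance: enhanced dynamic wedge factors, central axis
    dose, beam symmetry, focal spot triangulation from fields collimated at
    different head heights, and VMAT dose-rate/gantry-speed and MLC leaf-speed
    band tests.  Includes a region-of-interest engine with fractional pixel
    weighting, 50% field-edge detection, a seeded synthetic portal-image
    generator with controllable error injection (output, asymmetry tilt, focal
    spot displacement, wedge angle, per-segment monitor-unit fractions), an RT
    plan control-point meterset editor for VMAT error injection, and
    reproducibility, error-propagation, sensitivity-linearity and longitudinal
    concordance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
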