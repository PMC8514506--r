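Package: otrheo
Title: Optical-Tweezer Micro-Rheology and Interfacial Tension of
    Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optical-tweezer measurements of the
    material properties of phase-separated biomolecular condensates.
    Fits the two-component Burgers model of linear viscoelasticity to
    oscillatory micro-rheology data, calibrates trap stiffness and
    detector response from passive power spectra and active drives,
    extracts elastic and viscous moduli from driven bead traces,
    determines interfacial tension from two-trap droplet stretching and
    from bead-rupture micro-tensiometry, and tests the viscocapillary
    model of droplet fusion against measured fusion times.  Includes a
    synthetic-data generator that produces thermal bead-position traces,
    driven oscillation traces, stretching and rupture force ramps, and
    fusion-time datasets from known ground truth, so the full pipeline
    can be exercised without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
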