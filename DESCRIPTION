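Package: corneapuff
Title: Dynamic Corneal Hysteresis Analysis for Air-Puff OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies corneal viscoelasticity from air-puff swept-source
    optical coherence tomography (SS-OCT) M-scans. Segments anterior and
    posterior corneal surfaces, converts synchronized pressure-sensor
    readings to applied force via a strain-gauge calibration, builds dynamic
    force-versus-displacement hysteresis loops, and extracts the descriptor
    set used in ex vivo porcine-eye studies: maximum apex displacement,
    central corneal thickness before/at/after deformation, hysteresis area
    and ratio, and secant/low-strain/high-strain loading slopes. A
    Kelvin-Voigt phantom simulator with speckled M-scan rendering provides
    fully controlled synthetic cohorts for inflation-cycle and corneal
    cross-linking experiment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
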