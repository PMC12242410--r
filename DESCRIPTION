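Package: glycotube
Title: Glycocalyx-Driven Membrane Tube Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Energetics of membrane tubulation driven by a grafted polymer
    brush (the glycocalyx). Couples Canham-Helfrich bending, membrane
    tension, line tension and a vertical actin point force to the free
    energy of a polymer brush grafted on a cylinder-plus-hemispherical-cap
    membrane patch of fixed area. Provides energy-landscape scans over the
    tube shape parameter, classification of nontubular, metastable and
    tubular states, energy barriers, bisection root finding for critical
    grafting density and polymer length (binodal and spinodal), and one- and
    two-dimensional phase diagrams over membrane, brush and load parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
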