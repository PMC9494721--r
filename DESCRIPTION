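Package: nanosense
Title: Software-in-the-Loop Toolkit for Automated Nanopipette Intracellular Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and analyses the computer-vision and ion-current
    feedback stages of an automated nanopipette platform for adherent
    cells. Provides a synthetic-scene generator for defocused
    transparent-cell images, pipette-tip renders and approach-curve
    current traces; a contour-count (NOCC) focus measure built on hybrid
    triangle/Otsu segmentation; classical focus measures (Tenengrad,
    Energy, Brenner, Variance) with focus-curve quality metrics;
    pipette-tip localisation by triangle fitting; zero-mean normalised
    cross-correlation template matching with a nonovershoot descent
    controller; analytic approach-curve modelling with relative
    current-drop surface detection; detection scoring against nucleus
    ground truth; and a pipeline orchestrator with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    png,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
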