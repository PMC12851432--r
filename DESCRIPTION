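Package: empscan
Title: Automated SEM-EDS Counting and Classification of Airborne Elongated Mineral Particles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Workflow for quantifying airborne elongated mineral particles
    (EMPs) from automated scanning electron microscope imagery of air-sampled
    polycarbonate filters. Segments calibrated micrographs into particles,
    measures length and width as maximum and minimum Feret diameters, applies
    fiber-counting morphology criteria (aspect ratio at least 3, width below
    3 micrometres), classifies particles from EDS elemental mass percentages
    via the tetrahedral Tsi ratio Si/(Si+Al), and converts fiber counts to
    airborne concentrations in fibers per cubic centimetre with exact Poisson
    confidence intervals and a limit of detection. Includes a synthetic
    micrograph and EDS generator with ground truth, and a simulator of
    performance-evaluation filter standards spiked with known erionite mass
    fractions, so every stage is testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
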