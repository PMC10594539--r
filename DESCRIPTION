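Package: phosmap
Title: Simulation of Cortical Prosthetic Vision from Retinotopic Phosphene Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate the visual experience provided by cortical
    visual prostheses. Generates synthetic retinotopically mapped cortical
    surfaces (or reads real ones from tabular files), poses multi-electrode
    implant arrays on the cortex under anatomical and hardware constraints,
    projects electrodes into the visual field by k-nearest-neighbour inverse
    distance weighting, converts population receptive-field sizes to phosphene
    sizes through a sigmoidal activated-cortex model with cortical
    magnification, renders optotype and object stimuli through the resulting
    phosphene maps, relocates stimuli onto dense phosphene clusters with
    DBSCAN, and scores maps with complexity, mutual-information and
    concave-boundary-area metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
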