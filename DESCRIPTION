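Package: labyrinthometry
Title: Automated Morphometry of Inner-Ear Labyrinth Label Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures cochlear and vestibular anatomy from labeled 3-D
    voxel volumes of the bony labyrinth. The cochlea is spatially
    calibrated by principal component analysis to obtain basal diameters,
    regression-derived duct lengths, cochlear height, the modiolar axis
    and its angles to the semicircular canal planes; the vestibule is
    summarised by a least-squares ellipsoid fit giving principal
    diameters, central cross-section areas and plane-to-canal angles.
    Includes a synthetic labyrinth phantom generator with known ground
    truth, a metric-level cohort simulator for Meniere's disease study
    designs, and the accompanying group-comparison and correlation
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
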