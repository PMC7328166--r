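Package: gradgel
Title: Stiffness Readout of Gradient Polyacrylamide Hydrogels from
    Embedded Bead Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to calibrate and use bead-density readouts of local
    stiffness on polyacrylamide gradient hydrogels. Converts confocal
    image stacks of embedded fluorescent beads into spatial bead-density
    maps, fits spherical-indenter Hertz contact mechanics to atomic force
    microscopy (AFM) force curves to build matched stiffness maps, fits
    linear and logit bead-density-to-stiffness calibration curves with
    95% confidence bands, and predicts stiffness (with uncertainty) from
    bead density alone. Includes the downstream mechanobiology
    quantifications that such gradients are used for: four-case
    ratiometric two-channel adhesion images with Pearson colocalization,
    nuclear-to-cytoplasmic intensity ratios, cell area and roundness,
    adhesion-length morphometrics, and logarithmic adhesion-length versus
    stiffness modelling. A synthetic-fixture generator (bead phantoms,
    Hertz forward-model curves, paired gradient fields, adhesion and cell
    phantoms) makes the full pipeline testable without any instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
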