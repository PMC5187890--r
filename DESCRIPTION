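Package: aquaflux
Title: Osmotic Water Permeability and Hydrogen Peroxide Transport Analysis
    for Yeast Aquaporin Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for functional characterisation of
    aquaporins heterologously expressed in yeast: estimation of the osmotic
    water permeability coefficient (Pf) and its Arrhenius activation energy
    (Ea) from stopped-flow shrinkage traces, first-order hydrogen peroxide
    consumption kinetics from oxygen- and peroxide-electrode traces,
    line-profile quantification of relative membrane expression from
    fluorescence images, reduction of colorimetric assays (Bradford protein,
    Goth catalase, Tietze glutathione, DCF reactive oxygen species) through
    linear standard curves, and colony-survival statistics with the ANOVA /
    unpaired t-test comparison layer.  A synthetic-data module emulates every
    instrument readout with known ground truth so that all estimators are
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    deSolve,
    minpack.lm,
    jsonlite,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
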