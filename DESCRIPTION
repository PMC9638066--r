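Package: wheatvis
Title: UAV Multispectral Phenotyping of Wheat Yield and Nitrogen Use Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for plot-trial phenotyping of winter wheat
    from five-band (blue/green/red/red-edge/NIR) UAV imagery: empirical line
    radiometric calibration from reference panels, soil-background removal by
    Otsu thresholding of the VARI index, per-plot vegetation-index extraction
    (NDVI, NDRE, GNDVI, MTCI, mNDblue, repRVI and friends), nitrogen use
    efficiency traits (NPFP, aNUE), stage-wise correlation screening with a
    rank-based stage-generality score, and repeated N-stratified train/test
    evaluation of linear, stepwise-AIC and partial least-squares regression
    models. Ships a fully synthetic trial-scene generator (soil/canopy
    spectral mixtures over a 36-plot nitrogen-rate design) so every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    digest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
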