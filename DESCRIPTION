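Package: canolux
Title: Canopy Size, Incident Light, and Light Use Efficiency for
    Controlled-Environment Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to explain growth differences among leafy greens grown
    under electric light from top-down canopy images. Segments
    fluorescence-style canopy images into projected canopy size (PCS),
    fits three-parameter sigmoidal growth curves, converts photosynthetic
    photon flux density (PPFD) and photoperiod into daily light integrals,
    integrates per-plant incident light over the growing cycle, and derives
    light use efficiency (LUE), specific leaf area and canopy overlap
    ratio. Includes a species-by-PPFD multiple-regression layer with
    interaction pruning and a fully seeded synthetic-experiment generator
    (images, growth trajectories, physiology and harvest records) that
    provides ground truth for every stage.
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
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
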