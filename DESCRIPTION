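Package: uavdiv
Title: Multiscale Plant Species Diversity from UAV Photo and Quadrat Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes alpha-, beta- and gamma-diversity of grassland plant
    communities from two survey protocols: repeated nadir aerial photographs
    of fixed waypoints (presence frequency and dominance-weighted abundance
    proxies) and clipped ground quadrats (biomass and shoot density). Provides
    Shannon, Simpson, Pielou and richness indices under three species-proportion
    definitions, Sorensen and Cody turnover between adjacent precipitation bins,
    method-agreement regression between protocols, likelihood-ratio selection
    between linear and quadratic precipitation-response models, and a
    virtual-grassland simulator of both protocols (including small-stature
    species invisible to aerial photographs) so the whole pipeline can be
    exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
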