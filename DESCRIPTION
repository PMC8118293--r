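Package: beescape
Title: Pesticide Use and Habitat Quality Around Apiary Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Joint assessment of insecticide use and land-cover change around
    apiary (bee yard) sites. Apportions county-level insecticide use to
    crop-specific district application rates, totals use within dissolved
    1.6-km foraging buffers, fits linear use trends, builds risk-quotient
    weighted threat rasters for foliar insecticides, computes a
    distance-decay habitat degradation and quality model on 30-m land-cover
    grids, and summarises per-site Quality and Degradation Indices over
    time. Includes a synthetic landscape generator with known ground truth
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
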