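Package: greenequity
Title: Equity of Urban Greening Benefits for Fine-Particulate Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing who benefits when a city plants trees. Implements
    tree-cover to PM2.5 meta-models, a deterministic land-cover editing algorithm
    for the '3' (viewable trees) and '30' (neighbourhood canopy) components of the
    3-30-300 urban greening rule, dasymetric disaggregation of zone-level
    socio-demographic data to residential buildings, population-weighted exposure
    and tree-cover statistics per subgroup, and equity-gap reporting. Ships a
    synthetic-city generator with controllable spatial gradients so the whole
    pipeline runs and is testable without external data, plus published
    population-weighted exposure summaries for Aarhus and Paris.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
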