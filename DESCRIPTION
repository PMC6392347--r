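Package: icescape
Title: Circuit-Theory Landscape Connectivity for Island Metapopulations
    Under Sea-Ice Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models seasonal landscape connectivity across raster
    archipelagos where movement between islands depends on sea ice.
    Builds resistance surfaces from binned habitat probability-of-use on
    land and from sea-ice concentration at sea, solves all-pairs
    circuit-theory current flow with focal islands contracted to
    zero-resistance supernodes, assembles least-cost-path networks
    between islands, and ranks islands by raw and area-corrected
    current-flow centrality across climate scenarios and decades.
    Includes a synthetic archipelago and sea-ice scenario generator so
    the full pipeline is testable without external data, plus readers
    and writers for ESRI ASCII grids and CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
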