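Package: pndr
Title: Partial Network Decomposition of Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a utility function of a multilayer network -- chiefly
    the global efficiency over shortest paths -- into redundant, unique and
    synergistic contributions of its layers ("partial network decomposition").
    Provides the two-layer decomposition with per-pair classification and
    length-stratified profiles, the general N-layer machinery built on the
    antichain lattice and Moebius inversion, degree-preserving and
    geometry-preserving surrogate generators with ensemble significance
    testing, small-world propensity, and generators for the density-sweep and
    lattice-rewiring simulation experiments. Tidyverse-native: edge lists in,
    tibbles out, with broom-style tidy()/glance() and ggplot2 autoplot()
    methods.
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
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
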