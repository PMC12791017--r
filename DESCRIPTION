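Package: sedpyrite
Title: Non-Dimensional Diagenetic Modelling of Pyrite Burial and Sulfur
    Isotopes in Marine Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state advection-diffusion-reaction modelling of microbial
    sulfate reduction, sulfide-iron reaction and pyrite formation in marine
    sediment porewaters. Site boundary conditions are collapsed onto three
    non-dimensional governing variables (the organic-carbon-to-sulfate ratio,
    a modified Damkohler number, and reactive-iron delivery); the coupled
    sulfate and sulfide isotopologue boundary-value problem is solved on a
    non-dimensional depth grid to predict porewater profiles, pyrite content,
    burial flux and sulfur isotopic composition (delta-34S, Delta-pyrite).
    Includes global gridded upscaling with synthetic boundary-condition
    grids, one-at-a-time sensitivity tests, parameter-space heat maps, and a
    geologic-record pipeline (LOESS smoothing, bootstrap confidence bands and
    inversion of Delta-pyrite onto permissible parameter-space regions).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
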