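Package: enaminekin
Title: Microkinetic Selectivity Modelling for Dual-Site Enamine Organocatalysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the stereochemical outcome of aldol and
    Michael reactions catalysed by dimeric (two-active-site) proline-type
    organocatalysts. Converts relative Gibbs free-energy landscapes into
    mass-action reaction networks for the two competing catalytic cycles,
    integrates the stiff kinetic equations, and reports diastereomeric
    ratios, enantiomeric excesses and per-cycle flux partitions. Also
    implements pseudo-first-order rate-constant extraction from
    internal-referenced 19F NMR integral time courses, Boltzmann population
    analysis of enamine conformer ensembles, and an additive model of
    enantiocontrol for dimeric catalysts with exo/endo and L/D units.
    Synthetic-data generators for kinetic traces, free-energy landscapes and
    conformer ensembles support end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
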