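Package: ooidgrowth
Title: Nutrient-Limited Biofilm Growth and Lamination Models for Ooids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates nutrient-limited biofilm growth and
    organomineralisation of ooids (concentrically laminated carbonate
    grains). Provides the three-compartment volume ODE system for
    mineralised, inner-zone and outer-layer biotic material, closed-form
    solutions for the mineralisation front with and without microbial
    replenishment, the limiting-size analysis based on the stationarity
    cubic and the Greenspan active-rim width, constant-interval lamination
    ring generation and rendering, and least-squares recovery of growth
    parameters (magnification and sampling interval) from observed
    concentric ring radii. Includes a seeded synthetic ring generator for
    parameter-recovery studies and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
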