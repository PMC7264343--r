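Package: coastcarb
Title: Surface-Ocean Carbonate Chemistry Along Coastal Margins
Version: 0.1.0
Authors@R: person("coastcarb", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the marine CO2 system in surface coastal
    waters: a total-scale seawater carbonate speciation solver (DIC-TA,
    pCO2-TA and pH-TA input pairs with borate, water, phosphate and
    silicate alkalinity), the open-system vs closed-system temperature
    sensitivity framework with 25 degree normalization, Revelle-factor
    buffer analysis and the critical pH of maximum sensitivity,
    atmospheric-equilibrium predictions with observation-deviation
    correlations, air-sea CO2 gas exchange (Schmidt number, quadratic
    wind-speed transfer velocity, flux law), a daily mixed-layer box
    model with biological production and winter vertical mixing, and
    seeded generators for cruise-like transects and seasonal forcing so
    the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
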