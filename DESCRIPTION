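Package: nobsim
Title: Trait-Based Modeling of Soil Nitrite-Oxidizing Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the population dynamics, competition and nitrite
    oxidation of soil nitrite-oxidizer (NOB) functional types (Nitrospira-like
    K-strategists, chemolithotrophic and mixotrophic Nitrobacter-like
    r-strategists) with dual-Monod oxidation kinetics, quota-limited growth
    and environment-dependent (flexible) traits. Reconstructs steady-state
    ecological niches across nitrite, organic-carbon and oxygen gradients,
    maps measured environmental drivers (gross ammonification, soil
    respiration) to a two-compartment soil representation, runs multifactorial
    global-change treatment scenarios under 1-4 functional-type
    configurations, and generates synthetic factorial field datasets for
    end-to-end pipeline testing. Ships the observational summary tables of the
    underlying grassland global-change study as versioned fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
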