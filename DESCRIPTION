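Package: fbarebalance
Title: Rebalancing Measured Fluxes and Biomass Stoichiometry in Flux
    Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Flux balance analysis (FBA) problems can become infeasible
    when measured reaction rates are fixed in the model. This package
    restores feasibility by minimal, weighted adjustments of (i) the
    measured fluxes, (ii) the stoichiometric coefficients of the biomass
    reaction under a mass-conservation constraint, and (iii) the
    growth-associated maintenance (GAM) ATP demand, in linear- and
    quadratic-programming variants. It includes the supporting diagnostic
    workflow (elemental balances over measured rates, flux variability
    pre-checks), biomass-reaction introspection and restructuring (GAM
    extraction, macromolecule lumping), an SBML Level-3 FBC model reader
    and writer, a synthetic toy-model generator for validation, and a
    guideline driver that compares adjustment scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    yaml,
    jsonlite,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
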