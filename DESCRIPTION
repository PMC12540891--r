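Package: scfsol
Title: Solubility of Solid Drugs in Supercritical Carbon Dioxide
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic analysis of solid-solute solubility in supercritical
    carbon dioxide, built around a bundled 28-point isothermal dataset for the
    antimigraine drug sumatriptan. Implements the four classical density-based
    correlations (Chrastil, Bartle, Mendez-Santiago-Teja, Kumar-Johnston) with
    deterministic AARD-minimizing fits and the derived dissolution/vaporization/
    solvation enthalpies; solid-fluid equilibrium with the Peng-Robinson and
    Soave-Redlich-Kwong cubic equations of state under two-parameter van der
    Waals mixing rules, including closed-form fugacity coefficients and
    per-isotherm binary-interaction regression; a non-associating PC-SAFT
    equation of state (hard-chain plus dispersion) with analytic density and
    composition derivatives; a synthetic-data generator for parameter-recovery
    studies; and a pipeline that reproduces the study's result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
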