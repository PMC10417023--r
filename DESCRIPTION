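Package: neqsel
Title: Non-Equilibrium Free Energy Estimators and Kinase Selectivity Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical core of a non-equilibrium (NEQ) alchemical free energy
    workflow for relative binding free energies and kinase selectivity. Estimates
    free energy differences from forward/reverse switching work samples with the
    Jarzynski, Crooks Gaussian intersection and Bennett acceptance ratio
    estimators (bootstrap standard errors), assembles relative binding free
    energies over the thermodynamic cycle with conformer selection, converts
    IC50 inhibition data to experimental free energy differences through the
    Cheng-Prusoff equation, computes relative selectivity between kinases, and
    validates calculated against experimental values with generalized Deming
    (errors-in-variables) regression. Includes a Crooks-consistent synthetic
    study generator so the full pipeline is testable without molecular dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
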