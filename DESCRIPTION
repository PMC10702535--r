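Package: sasamc
Title: Coarse-Grained SASA-Based Monte Carlo Simulation of Salt Effects
    on Solute Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implicit-water, implicit-salt Metropolis Monte Carlo
    simulation of rigid coarse-grained solutes (caffeine by default) whose
    potential energy depends on the instantaneous solvent-accessible
    surface area (SASA), a salt-specific transfer free energy and the
    cosolute concentration.  Supports canonical and grand-canonical
    ensembles with single-molecule, cluster and insertion/deletion moves,
    Widom excess chemical potentials, virtual-volume pressures and radial
    distribution functions.  Analysis layers recover the full ternary
    water-solute-salt thermodynamics: Kirkwood-Buff integral inversion,
    preferential binding coefficients, activity-coefficient models with
    Gibbs-Duhem-consistent water activity, and a vapor-pressure-osmometry
    style pipeline (residual osmolality and solute-concentration dependent
    salting-out constants) applicable to both experimental tables and
    simulation output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
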