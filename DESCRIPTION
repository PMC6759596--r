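Package: saltroot
Title: Biophysical Simulation of Ion and Water Transport in Salt-Stressed
    Plant Roots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled transport of Na+, K+, Cl-, H+ and water
    through a discretized Arabidopsis root under salt stress. The root is
    represented as annular tissue rings (epidermis, cortex, endodermis,
    xylem parenchyma, xylem) by axial layers, each divided into apoplastic,
    cytosolic and vacuolar compartments, with two developmental zones
    (apex and mature, the latter carrying Casparian strip and suberin
    barriers). Membrane transport combines Goldman-Hodgkin-Katz channel
    fluxes with Boltzmann voltage gating, four-state carrier cycles for
    pumps and symporters, and mass-action Na+/H+ antiporters; apoplastic
    and symplastic transport follows an extended Nernst-Planck law with
    convection; electric potentials enforce local electroneutrality as
    algebraic constraints of a stiff differential-algebraic system. The
    package enumerates spatial scenarios for plasma-membrane Na+/H+
    antiporter (SOS1) activity, runs strength sweeps, classifies outcomes
    against wild-type references, and provides a two-stage constrained
    parameter-estimation procedure with sensitivity screening, together
    with a synthetic target-table generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
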