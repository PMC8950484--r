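Package: oglycosim
Title: Kinetic Simulation and Parameter Estimation of Mucin-Type
    O-Glycan Biosynthesis in the Golgi
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based generation of mucin-type O-linked glycosylation
    reaction networks for engineered CHO cell lines, deterministic
    simulation of glycan processing through a four-compartment Golgi
    model with competing-substrate Michaelis-Menten kinetics, and
    estimation of enzyme kinetic constants and compartmental enzyme
    concentrations by a stochastic-ranking evolution strategy fitted
    against observed trans-Golgi-network glycan profiles.  Includes a
    condensed-IUPAC glycan string parser, a bundled enzyme/reaction-rule
    table, donor-sugar and enzyme-localization tables, experiment
    configurations for 25 transfection experiments, charge-based
    mass-spectrometry intensity adjustment, and a synthetic-profile
    generator for end-to-end testing of the estimation machinery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
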