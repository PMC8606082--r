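Package: ordflux
Title: Kinetics of ORD-Mediated PS/PI(4)P Exchange Between Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic simulation and assay analysis for
    lipid transfer proteins of the ORP/Osh family that exchange
    phosphatidylserine (PS) and PI(4)P between two membranes. Implements
    a six-reaction exchange cycle as a stiff ODE system with the
    membranes treated as constant boundary species, parameter sweeps of
    lipid capture rates with initial-rate extraction and acceleration
    factors, normalization of FRET dequenching/quenching transfer traces
    into absolute transferred-lipid time courses with initial
    velocities, titration-curve fitting (competitive displacement
    [L]50, Boltzmann thermal-shift melting temperature, saturation
    membrane binding), and seeded synthetic-data generators with known
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
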