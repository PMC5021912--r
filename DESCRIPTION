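Package: bipapsim
Title: Two-Compartment Lung Simulation of Bi-Level Positive Airway
    Pressure Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of a bi-level positive airway pressure
    (BIPAP) mechanical-ventilation circuit driving two lungs. Each airway
    is lumped into an equivalent orifice carrying compressible (subsonic
    or choked) mass flow, and each lung is a variable-volume container of
    isothermal ideal gas with linear respiratory compliance. The package
    integrates the coupled pressure/volume/mass differential equations
    over breath cycles, computes the instantaneous flow-split ratio
    between the two lungs and the per-breath tidal-volume share, and runs
    one-at-a-time parameter sweeps over ventilator settings (IPAP, EPAP,
    breath rate, inspiratory time, rise time) and lung parameters
    (compliance, orifice diameter).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
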