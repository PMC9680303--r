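Package: biofiltr
Title: Practical Transient Modelling of Packed-Bed Biofilters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical transient model for gas-phase packed-bed biofilters
    removing volatile organic compounds. The bed is discretized into a cascade
    of well-mixed segments; pollutant uptake into the biofilm is closed with a
    first-order diffusion-reaction profile (Thiele-modulus tanh flux), giving a
    two-parameter per-segment solution with a closed-form steady state. Includes
    derived-parameter calculators (effective biofilm diffusivity, lumped
    first-order rate constant, per-segment attenuation and rate constants),
    biofilm concentration profiles, piecewise-constant inlet schedules with an
    exponential-propagation integrator, a bundled benzene benchmark dataset for
    validation against published steady-state measurements, a YAML run-config
    reader, and CSV exporters plus a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
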