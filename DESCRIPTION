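Package: physdep
Title: Typed Physical-Dependency Networks for Lumped-Parameter Biophysical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, validate, and execute typed networks of biophysical
    dependencies in the bond-graph / network-thermodynamics tradition. Physical
    entities and processes bear property instances (amounts, momenta, forces,
    flow rates, constitutive proportionalities) across the electrical, fluid,
    chemical, and mechanical domains; dependency instances bind properties to
    named roles under per-kind signatures (resistive, capacitive, inductive,
    mass-action, diffusion, transformer/transducer, transactor, boundary and
    state dependencies). Validated networks compile to explicit ODE systems
    with deterministic causality assignment and algebraic scheduling, integrate
    with a fixed-step classical Runge-Kutta solver, support steady-state
    location and qualitative up/down perturbation (sign propagation) with a
    numeric cross-check, and export as YAML model documents and RDF Turtle
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), deSolve, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'physdep-package.R'
    'errors.R'
    'taxonomy.R'
    'laws.R'
    'classes.R'
    'network.R'
    'compiler.R'
    'simulator.R'
    'qualitative.R'
    'fixtures.R'
    'io.R'
    'cli.R'
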