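---
title: "Typed physical-dependency networks: model, compiler, and diagnostics"
author: "physdep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed physical-dependency networks: model, compiler, and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physdep)
```

## The formalism

`physdep` executes lumped-parameter biophysical models written as *typed
dependency networks*, the representation used by network thermodynamics and
bond-graph modelling. A model consists of:

* **entities** (a portion of blood, a capacitor, a species pool) and
  **processes** (a reaction, a charging event) that *bear*
* **property instances** — each an instance of a property class drawn from a
  fixed taxonomy of four biophysical domains (electrical, fluid, chemical,
  mechanical) crossed with dynamical categories:

  | category | electrical | fluid | chemical | mechanical |
  |---|---|---|---|---|
  | force (effort) | potential (V) | pressure (Pa) | chemical potential (J/mol) | force (N) |
  | flow | current (A) | volume flow (m³/s) | molar flow (mol/s) | velocity (m/s) |
  | amount | charge (C) | volume (m³) | molar amount (mol) | displacement (m) |
  | momentum | flux linkage (Wb) | fluid momentum (Pa·s) | — | momentum (N·s) |

* **dependency instances** — occurrences of physical-law classes that bind
  property instances to named roles (`flow_player`, `force_player_high`,
  `amount_player`, `constitutive`, ...), each with a fixed signature and a
  residual equation:

  | kind | equation | constitutive |
  |---|---|---|
  | `boundary_flow` | d(amount)/dt = Σ inflow − Σ outflow | — |
  | `boundary_force` | d(momentum)/dt = Σ force_high − Σ force_low | — |
  | `summation` | whole = Σ parts | — |
  | `spatial` | derived = a · primary^b | a, b |
  | `resistive` | flow = (force_high − force_low)/R | resistance (or conductance) |
  | `mass_action` | flow = k_f Π fwd^s − k_r Π rev^s | rate constants |
  | `diffusion` | flow = k_d (amount_high − amount_low) | rate constant |
  | `michaelis_menten` | flow = V_max · a/(K_m + a) | V_max, K_m |
  | `transformer` / `transducer` | force₂ = m·force₁, flow₁ = m·flow₂ | modulus |
  | `capacitive` | force = amount/C (+ reference) | capacitance |
  | `inductive` | flow = momentum/L | inductance |
  | `transactor` | target = c · source | coefficient (any sign) |

* **sources** — prescribed boundary conditions driving force or flow
  properties with constant, step, or sine waveforms.

The chemical domain deliberately has **no momentum** (and hence no
inductance): there is no established chemical inductive analogue, and asking
for one fails loudly (`E_NO_SUCH_PROPERTY`) rather than returning a silent
zero.

Cross-domain analogies are first-class: `analogOf()` maps any dynamical
property class onto its counterpart in another domain, and the canonical
constitutive units are *derived* from the defining relations
(resistance = force/flow, capacitance = amount/force, inductance =
momentum/flow, rate constant = flow/amount), which the test suite verifies by
symbolic reduction to SI base dimensions — mechanical inductance
`N·s/(m/s)` reduces to `kg`, i.e. inductance of a translating body *is* its
mass.

### Conventions worth knowing

* **Sign convention.** Positive flow always runs from the high-force player
  to the low-force player; `boundary_flow` counts flows positively into its
  `target_player` amount and negatively out of its `source_player` amount.
  One convention everywhere prevents silent sign errors.
* **Force differentials** are represented as two bound force properties
  (`force_player_high`, `force_player_low`), never as an anonymous
  Δ-property, so every symbol in a model remains attached to a bearer. Where
  a law is stated against a reference ("ground"), bind a zero-valued constant
  force source, or omit the optional low player of a capacitive dependency.
* **Rate-constant vs resistance pairing.** Amount-driven flow laws
  (mass action, diffusion) carry rate constants; force-driven laws (the
  Ohm analogues) carry resistances. Conductance is accepted as a constitutive
  player and normalised to its reciprocal resistance at compile time.
* **Inductive storage is factored in two.** The classical inductive relation
  between a force differential and stored momentum is realised as the pair
  `boundary_force` (d momentum/dt = Δforce) plus `inductive`
  (flow = momentum/L); that is the only factoring realisable in an explicit
  ODE formalism, and it makes Newton's second law a two-dependency model
  (see the Newton rig in the test suite: velocity slope is exactly F/m).

## Validation

`validateNetwork()` returns findings as data (never throws): role-signature
violations (missing/extra/unknown roles, wrong player categories),
domain-rule violations (single-domain kinds must be homogeneous; transducers
must span exactly two domains, one per side), non-positive constitutive
values, sources driving non-rate properties, part-of cycles, and
boundary-driven states without initial values. A cross-domain *transactor*
is downgraded to a warning: transactors are explicitly wild cards for
mechanistically unknown couplings (the baroreflex fixture couples a fluid
pressure to a cardiac rate property), and rejecting them would forbid their
main use.

## Compilation to an ODE system

`compileNetwork()` performs three deterministic steps:

1. **State identification** — every amount moved by a `boundary_flow` and
   every momentum accumulated by a `boundary_force` becomes a state, ordered
   by id.
2. **Causality assignment** — each non-boundary dependency computes exactly
   one output player (transformer-type kinds compute two: side-2 force and
   side-1 flow). Every other dynamical property must be a state, a
   source, a *prescribed constant*, or the output of exactly one dependency;
   otherwise `E_OVERDETERMINED` / `E_UNDERDETERMINED` names the property. A
   state-category property with a set value that nothing computes is treated
   as a prescribed constant — this is what lets a purely algebraic model
   (e.g. part volumes feeding a summation) run without artificial sources,
   which the source mechanism could not supply since sources drive only rate
   properties.
3. **Scheduling** — the (dependency, output) items are topologically sorted;
   ties break by dependency id, so identical networks always compile to
   identical schedules. Transformer outputs are scheduled *independently*,
   which is what lets a transducer drive a resistive load: side-2 force is
   computable before the load flow, which in turn feeds side-1 flow. A true
   algebraic cycle (no storage node breaking the loop) raises
   `E_ALGEBRAIC_LOOP` listing the offending dependencies — loops are
   rejected, not solved; every well-posed storage-causality model is
   loop-free, and an honest failure beats a fragile fixed-point iteration.

Transformer causality is fixed (inputs: side-1 force, side-2 flow). A model
needing the reverse orientation must swap its sides; this avoids a
bond-graph-style causality search and is a documented limitation.

## Numerical integration

`integrateODE()` is a fixed-step classical 4th-order Runge–Kutta integrator.
Fixed-step RK4 was chosen over adaptive solvers because trajectories are then
bit-stable and reproducible across runs and platforms, which the analogy and
conservation tests exploit (`deSolve`'s adaptive `lsoda` serves as an
independent cross-check in the test suite, not as the implementation).
Trajectories record *all* properties — forces and flows, not just states —
because those are the physiologically named quantities.

Verified numerical behaviour (all recomputed by the test suite and
`scripts/acceptance.R`):

* RC charging matches `1 − exp(−t/RC)` to < 1e−6 at dt = 1e−3 (measured
  ≈ 4e−15);
* halving dt cuts the error ≈ 16-fold (measured order ≈ 4.0);
* a closed two-compartment exchange conserves total amount to < 1e−12
  relative over 10⁴ steps (the source/target formulation makes Σ d/dt ≡ 0
  analytically);
* the LC oscillator drifts < 1e−6 in energy over 10 periods at
  dt = period/1000 and oscillates at 2π√(LC) to < 0.1 %.

`steadyState()` relaxes under constant sources until the max-norm of the
state derivative falls below `tol` (default 1e−12); an undamped oscillator
correctly reports `E_NO_STEADY_STATE`. Negative amounts are not clamped:
mass-action raises `E_NEGATIVE_STATE` below −1e−9, surfacing instability
instead of masking it.

## Qualitative up/down perturbation

`propagateSign()` performs solver-free perturbation reasoning over the signed
influence graph (`influenceEdges()` unrolls each dependency into causal
edges). The semantics is the **sign-sum over all simple paths** from the
perturbed node, in the algebra {+, −, 0, ?} where conflicting contributions
absorb to `?`. Simple-path semantics, rather than naive fixed-point
iteration over the cyclic graph, is a deliberate choice: every storage loop
is a negative feedback loop (amount → force → flow → amount), and iterating
signs around it would poison the entire loop to `?`, erasing exactly the
predictions — "drive up ⇒ stored amount up, force up" — that make the method
useful. Path enumeration is exponential in the worst case but the networks
in scope are small.

`checkAgainstNumeric()` is the validation harness: it perturbs a source by a
relative step (default 1 %), recomputes both steady states, classifies each
property's numeric change as +/−/0 (tolerance 1e−9 · scale), and grades each
qualitative prediction as `agree`, `conservative` (`?`, or a predicted
influence whose steady-state change is exactly zero — e.g. the RC charging
current, which responds transiently but returns to zero), `missed`, or
`contradict`. Soundness means `contradict` never occurs; on every shipped
fixture the strict agreement rate over numerically changing properties
is 100 %. Perturbations target source properties: a constitutive parameter
has no sign-algebra edge (its influence sign depends on the sign of the
state it multiplies), so parameter perturbations are meaningful only in the
numeric harness.

## Synthetic fixtures: what they emulate, and what they do not

The built-in fixtures are the package's stand-in for external data; their
defaults are chosen as minimal canonical parameterisations of each textbook
circuit rather than as physiological calibrations:

* `rc_circuit` (R = 2, C = 0.5, E0 = 1, q0 = 0) — time constant RC = 1 and a
  unit steady state, so analytic comparisons are O(1);
* `windkessel` (R = C = Q0 = 1) — the fluid analog, steady pressure Q0·R = 1;
* `lc_oscillator` (L = C = 1, q0 = 1) — unit energy, period 2π;
* `mass_action_pair` (k_f = 2, k_r = 1, A0 = 1, B0 = 2) — sits exactly at
  detailed balance, so the compiled system is analytically static;
* `chemo_mech_transducer`, `baroreflex_toy` (coefficient −0.5),
  `multiscale_sum` — algebraic exemplars of transduction, wild-card control,
  and part-whole summation.

`randomizedNetwork(seed, ...)` grows a random capacitor tree with resistive
links and one source; by construction every draw validates, compiles, and
integrates, which the tests assert over hundreds of seeds.

These fixtures exercise the formalism, not the physiology: passing tests
demonstrate correctness of validation, compilation, integration, and sign
reasoning on ideal proportional elements. They say nothing about
non-proportional real-world behaviour — pressure-dependent vascular
resistance, gated conductances, saturating transport beyond the single
sanctioned Michaelis–Menten form — all of which are outside the proportional
core by design.

## Problem sizes and tolerances

The suites run the RC comparison on 5 001 grid points, conservation checks
over 10⁴ steps, the LC run over 10 periods at 1 000 steps/period, the
randomized-network sweep over 200 seeds, and the law-algebra properties over
1 000 random draws each; the whole test suite completes in well under a
minute on one core. Machine-precision claims are asserted at rounding-noise
thresholds (e.g. 1e−13 for the Newton rig slope, bit-identity for the
matched RC/Windkessel discharge trajectories, which execute identical
floating-point arithmetic by construction).

## Known limitations

* No DAE support, implicit loops, events, or stiff detection; fixed
  transformer causality.
* No continuum (PDE) physics; discrete entities only.
* No general unit conversion — canonical units plus dimensional checking
  only.
* The YAML dialect and the role vocabulary are this package's
  concretisation of the dependency schema; the RDF export therefore ships a
  deliberately non-resolvable `urn:x-physdep:` placeholder namespace, and
  users targeting a published ontology must supply their own IRI map
  (`exportRDF(net, iriMap = ...)`).
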