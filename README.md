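# physdep

Typed physical-dependency networks for lumped-parameter biophysical models.

Physiological models — hemodynamics, reaction kinetics, electrophysiological
circuits, muscle mechanics — are overwhelmingly built from the same small set
of classical physical laws applied across domains: Ohm-analogue resistive
flow, Hooke-analogue capacitive storage, inductive (kinetic) storage,
mass-action and diffusion fluxes, transformer/transducer couplings, and
accumulation ("boundary") laws that integrate flows into amounts and forces
into momenta. `physdep` makes that structure explicit and executable. It is
aimed at modellers and knowledge engineers who want the *semantics* of a
lumped-parameter model — which property plays which role in which law — to be
machine-checkable, simulatable, and exportable as annotations, rather than
implicit in equation code.

A model is a typed network: **entities** and **processes** bear **property
instances** (generalized force, flow, amount, momentum, plus constitutive
proportionalities) in one of four domains (electrical, fluid, chemical,
mechanical); **dependency instances** bind properties to named roles under
per-kind signatures. The core relations, in the field's standard notation:

- resistive: `f = (e_high − e_low) / R`
- capacitive: `e = q / C`  inductive: `f = p / L`
- boundary: `dq/dt = Σ f_in − Σ f_out`, `dp/dt = Σ e_high − Σ e_low`
- mass action: `f = k_f Π a_i^{s_i} − k_r Π a_j^{s_j}`; diffusion: `f = k_d Δa`
- transformer/transducer: `e₂ = m·e₁`, `f₁ = m·f₂` (so `e₁f₁ = e₂f₂`)
- transactor wild card: `y = c·x` (any sign, any category pair)

From a validated network the package compiles an explicit ODE system
(deterministic causality assignment + topological scheduling), integrates it
with a bit-stable fixed-step RK4, locates steady states, performs solver-free
qualitative up/down perturbation with a numeric cross-check, and reads/writes
a versioned YAML model dialect plus RDF Turtle annotations
(`hasFlowPlayer`, `hasForcePlayer`, `hasConstitutiveProportionality`, ...).

## Worked example: a two-element Windkessel

```r
library(physdep)
net <- makeFixture("windkessel", list(R = 1.5, C = 2, Q0 = 0.8))
net
#> ModelNetwork 'windkessel': 2 entities, 0 processes, 7 properties, 4 dependencies, 2 sources

sys <- compileNetwork(net)
sys
#> ODESystem: 1 state(s), 2 scheduled step(s)
#>   d(wk_volume)/dt = wk_inflow - wk_outflow
#>   wk_pressure = capacitive(wk_volume, wk_C)   # wk_dep_cap
#>   wk_outflow = resistive(wk_pressure, wk_sink_pressure, wk_R)   # wk_dep_res

round(unlist(steadyState(sys)$values), 6)
#>             wk_C        wk_inflow       wk_outflow      wk_pressure
#>              2.0              0.8              0.8              1.2
#>             wk_R wk_sink_pressure        wk_volume
#>              1.5              0.0              2.4
```

At steady state the outflow balances the prescribed inflow (0.8 m³/s), the
pressure settles at `Q0·R = 0.8 × 1.5 = 1.2 Pa`, and the stored volume at
`C·Q0·R = 2.4 m³` — the analytic solution of the compliance–resistance
balance. Qualitative perturbation agrees with the numeric oracle:

```r
checkAgainstNumeric(net, "wk_inflow")
#>           property qualitative numeric agreement
#> 1        wk_inflow           +       +     agree
#> 2       wk_outflow           +       +     agree
#> 3      wk_pressure           +       +     agree
#> 4 wk_sink_pressure           0       0     agree
#> 5        wk_volume           +       +     agree
```

Other built-in fixtures (`fixtureNames()`): an RC charging circuit (the
electrical analog of the Windkessel — matched parameters give bit-identical
trajectories), an LC oscillator, a reversible mass-action pair, a
chemo-mechanical transducer, a baroreflex transactor toy, and a part-volume
summation. Models round-trip through `writeModel()` / `readModel()`, export
with `exportRDF()`, and everything is scriptable from a shell via
`inst/cli/physdep.R` (`validate`, `simulate`, `steady`, `perturb`,
`export-rdf`, `fixture`).

See `vignettes/physdep-methods.Rmd` for the modelling formalism, numerical
choices, and limitations.

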