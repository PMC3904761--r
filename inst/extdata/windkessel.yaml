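format: physdep-model
version: '1.0'
metadata:
  name: windkessel
  description: 'Two-element fluid Windkessel: compliance + peripheral resistance'
entities:
  - id: wk_artery
    label: Compliant arterial compartment
    domain: fluid
  - id: wk_sink
    label: Venous sink (reference pressure)
    domain: fluid
properties:
  - id: wk_inflow
    class: fluid.flow
    bearer: wk_artery
    unit: m^3/s
  - id: wk_pressure
    class: fluid.force
    bearer: wk_artery
    unit: Pa
  - id: wk_volume
    class: fluid.amount
    bearer: wk_artery
    unit: m^3
    value: 0.0
  - id: wk_outflow
    class: fluid.flow
    bearer: wk_artery
    unit: m^3/s
  - id: wk_sink_pressure
    class: fluid.force
    bearer: wk_sink
    unit: Pa
  - id: wk_R
    class: fluid.constitutive.resistance
    bearer: wk_artery
    unit: Pa/(m^3/s)
    value: 1.0
  - id: wk_C
    class: fluid.constitutive.capacitance
    bearer: wk_artery
    unit: m^3/Pa
    value: 1.0
dependencies:
  - id: wk_dep_cap
    kind: capacitive
    bindings:
      - role: force_player_high
        property: wk_pressure
      - role: amount_player
        property: wk_volume
      - role: constitutive
        property: wk_C
  - id: wk_dep_res
    kind: resistive
    bindings:
      - role: flow_player
        property: wk_outflow
      - role: force_player_high
        property: wk_pressure
      - role: force_player_low
        property: wk_sink_pressure
      - role: constitutive
        property: wk_R
  - id: wk_dep_in
    kind: boundary_flow
    bindings:
      - role: target_player
        property: wk_volume
      - role: flow_player
        property: wk_inflow
  - id: wk_dep_out
    kind: boundary_flow
    bindings:
      - role: source_player
        property: wk_volume
      - role: flow_player
        property: wk_outflow
sources:
  - property: wk_inflow
    waveform: constant
    level: 1.0
  - property: wk_sink_pressure
    waveform: constant
    level: 0.0
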