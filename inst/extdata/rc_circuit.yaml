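format: physdep-model
version: '1.0'
metadata:
  name: rc_circuit
  description: 'Electrical RC charging circuit: resistive + capacitive + boundary
    flow'
entities:
  - id: rc_source
    label: Voltage source node
    domain: electrical
  - id: rc_resistor
    label: Series resistor
    domain: electrical
  - id: rc_capacitor
    label: Capacitor
    domain: electrical
processes:
  - id: rc_charging
    label: Capacitor charging
    participants:
      - rc_source
      - rc_resistor
      - rc_capacitor
properties:
  - id: rc_src_force
    class: electrical.force
    bearer: rc_source
    unit: V
  - id: rc_cap_force
    class: electrical.force
    bearer: rc_capacitor
    unit: V
  - id: rc_charge
    class: electrical.amount
    bearer: rc_capacitor
    unit: C
    value: 0.0
  - id: rc_current
    class: electrical.flow
    bearer: rc_charging
    unit: A
  - id: rc_R
    class: electrical.constitutive.resistance
    bearer: rc_resistor
    unit: V/A
    value: 2.0
  - id: rc_C
    class: electrical.constitutive.capacitance
    bearer: rc_capacitor
    unit: C/V
    value: 0.5
dependencies:
  - id: rc_dep_res
    kind: resistive
    bindings:
      - role: flow_player
        property: rc_current
      - role: force_player_high
        property: rc_src_force
      - role: force_player_low
        property: rc_cap_force
      - role: constitutive
        property: rc_R
  - id: rc_dep_cap
    kind: capacitive
    bindings:
      - role: force_player_high
        property: rc_cap_force
      - role: amount_player
        property: rc_charge
      - role: constitutive
        property: rc_C
  - id: rc_dep_bnd
    kind: boundary_flow
    bindings:
      - role: target_player
        property: rc_charge
      - role: flow_player
        property: rc_current
sources:
  - property: rc_src_force
    waveform: constant
    level: 1.0
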