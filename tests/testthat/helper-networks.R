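# Shared constructors and closed-form oracles used across test files.

errorsOf <- function(net) {
  rep <- validateNetwork(net)
  rep[rep$level == "error", , drop = FALSE]
}

# Closed-form RC charging: q(t) = C*E0*(1 - exp(-t/(R*C))), force = q/C.
rcClosedForm <- function(t, R, C, E0, q0 = 0) {
  qInf <- C * E0
  qInf + (q0 - qInf) * exp(-t / (R * C))
}

# Closed two-compartment exchange: two capacitors joined by one resistor,
# no sources. Total charge is exactly conserved.
makeTwoCompartment <- function(q1 = 1.5, q2 = 0.5, R = 1, C1 = 1, C2 = 2) {
  modelNetwork(
    entities = list(entityNode("tc_a", "electrical"), entityNode("tc_b", "electrical")),
    properties = list(
      propertyInstance("tc_q1", "electrical.amount", "tc_a", q1),
      propertyInstance("tc_q2", "electrical.amount", "tc_b", q2),
      propertyInstance("tc_f1", "electrical.force", "tc_a"),
      propertyInstance("tc_f2", "electrical.force", "tc_b"),
      propertyInstance("tc_flow", "electrical.flow", "tc_a"),
      propertyInstance("tc_R", "electrical.constitutive.resistance", "tc_a", R),
      propertyInstance("tc_C1", "electrical.constitutive.capacitance", "tc_a", C1),
      propertyInstance("tc_C2", "electrical.constitutive.capacitance", "tc_b", C2)),
    dependencies = list(
      dependencyInstance("tc_cap1", "capacitive",
                         list(force_player_high = "tc_f1", amount_player = "tc_q1",
                              constitutive = "tc_C1")),
      dependencyInstance("tc_cap2", "capacitive",
                         list(force_player_high = "tc_f2", amount_player = "tc_q2",
                              constitutive = "tc_C2")),
      dependencyInstance("tc_res", "resistive",
                         list(flow_player = "tc_flow", force_player_high = "tc_f1",
                              force_player_low = "tc_f2", constitutive = "tc_R")),
      dependencyInstance("tc_bnd", "boundary_flow",
                         list(source_player = "tc_q1", target_player = "tc_q2",
                              flow_player = "tc_flow"))),
    metadata = list(name = "two_compartment", description = "closed exchange"))
}

# Newton test rig: constant force on a mass; velocity = momentum / m.
makeNewtonRig <- function(F = 2, m = 0.5) {
  modelNetwork(
    entities = list(entityNode("nw_ball", "mechanical")),
    properties = list(
      propertyInstance("nw_applied_force", "mechanical.force", "nw_ball"),
      propertyInstance("nw_momentum", "mechanical.momentum", "nw_ball", 0),
      propertyInstance("nw_velocity", "mechanical.flow", "nw_ball"),
      propertyInstance("nw_mass", "mechanical.constitutive.inductance", "nw_ball", m)),
    dependencies = list(
      dependencyInstance("nw_ind", "inductive",
                         list(flow_player = "nw_velocity", momentum_player = "nw_momentum",
                              constitutive = "nw_mass")),
      dependencyInstance("nw_bnd", "boundary_force",
                         list(momentum_player = "nw_momentum",
                              force_player_high = "nw_applied_force"))),
    sources = list(sourceSpec("nw_applied_force", "constant", level = F)),
    metadata = list(name = "newton_rig", description = "f = ma as boundary_force + inductive"))
}

# Two opposing influence paths onto one diffusion flux: a chemical-potential
# source raises both pool amounts via transactors (coefficients c1, c2), and
# the flux depends positively on one pool, negatively on the other.
makeOpposingPaths <- function(c1 = 1, c2 = 0.5, kd = 1) {
  modelNetwork(
    entities = list(entityNode("op_cell", "chemical")),
    properties = list(
      propertyInstance("op_drive", "chemical.force", "op_cell"),
      propertyInstance("op_amt_a", "chemical.amount", "op_cell"),
      propertyInstance("op_amt_b", "chemical.amount", "op_cell"),
      propertyInstance("op_flux", "chemical.flow", "op_cell"),
      propertyInstance("op_c1", "chemical.constitutive.coefficient", "op_cell", c1),
      propertyInstance("op_c2", "chemical.constitutive.coefficient", "op_cell", c2),
      propertyInstance("op_kd", "chemical.constitutive.rate_constant", "op_cell", kd)),
    dependencies = list(
      dependencyInstance("op_t1", "transactor",
                         list(source_player = "op_drive", target_player = "op_amt_a",
                              constitutive = "op_c1")),
      dependencyInstance("op_t2", "transactor",
                         list(source_player = "op_drive", target_player = "op_amt_b",
                              constitutive = "op_c2")),
      dependencyInstance("op_diff", "diffusion",
                         list(flow_player = "op_flux", source_player = "op_amt_a",
                              target_player = "op_amt_b", constitutive = "op_kd"))),
    sources = list(sourceSpec("op_drive", "constant", level = 1)),
    metadata = list(name = "opposing_paths", description = "conflicting sign paths"))
}

# linearly interpolated upward zero crossings of a sampled signal
zeroCrossings <- function(t, x) {
  i <- which(x[-length(x)] < 0 & x[-1] >= 0)
  t[i] + (t[i + 1] - t[i]) * (-x[i]) / (x[i + 1] - x[i])
}
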