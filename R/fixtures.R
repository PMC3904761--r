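# Canonical fully-parameterized model networks for tests, docs, and the CLI,
# plus a randomized-network generator for property-style testing.

.fixtureBuilders <- list(

  # Electrical RC: constant force source -> resistor -> capacitor.
  # dq/dt = (E0 - q/C)/R
  rc_circuit = function(R = 2, C = 0.5, E0 = 1, q0 = 0) {
    if (R <= 0 || C <= 0) physdepStop("E_BAD_CONSTITUTIVE", "rc_circuit requires R > 0 and C > 0")
    modelNetwork(
      entities = list(entityNode("rc_source", "electrical", "Voltage source node"),
                      entityNode("rc_resistor", "electrical", "Series resistor"),
                      entityNode("rc_capacitor", "electrical", "Capacitor")),
      processes = list(processNode("rc_charging", c("rc_source", "rc_resistor", "rc_capacitor"),
                                   "Capacitor charging")),
      properties = list(
        propertyInstance("rc_src_force", "electrical.force", "rc_source"),
        propertyInstance("rc_cap_force", "electrical.force", "rc_capacitor"),
        propertyInstance("rc_charge", "electrical.amount", "rc_capacitor", q0),
        propertyInstance("rc_current", "electrical.flow", "rc_charging"),
        propertyInstance("rc_R", "electrical.constitutive.resistance", "rc_resistor", R),
        propertyInstance("rc_C", "electrical.constitutive.capacitance", "rc_capacitor", C)),
      dependencies = list(
        dependencyInstance("rc_dep_res", "resistive",
                           list(flow_player = "rc_current", force_player_high = "rc_src_force",
                                force_player_low = "rc_cap_force", constitutive = "rc_R")),
        dependencyInstance("rc_dep_cap", "capacitive",
                           list(force_player_high = "rc_cap_force", amount_player = "rc_charge",
                                constitutive = "rc_C")),
        dependencyInstance("rc_dep_bnd", "boundary_flow",
                           list(target_player = "rc_charge", flow_player = "rc_current"))),
      sources = list(sourceSpec("rc_src_force", "constant", level = E0)),
      metadata = list(name = "rc_circuit",
                      description = "Electrical RC charging circuit: resistive + capacitive + boundary flow"))
  },

  # Fluid two-element Windkessel: prescribed inflow, compliant vessel,
  # resistive drain to a zero-pressure sink. Steady: P = Q0*R, V = C*Q0*R.
  windkessel = function(R = 1, C = 1, Q0 = 1, V0 = 0) {
    if (R <= 0 || C <= 0) physdepStop("E_BAD_CONSTITUTIVE", "windkessel requires R > 0 and C > 0")
    modelNetwork(
      entities = list(entityNode("wk_artery", "fluid", "Compliant arterial compartment"),
                      entityNode("wk_sink", "fluid", "Venous sink (reference pressure)")),
      properties = list(
        propertyInstance("wk_inflow", "fluid.flow", "wk_artery"),
        propertyInstance("wk_pressure", "fluid.force", "wk_artery"),
        propertyInstance("wk_volume", "fluid.amount", "wk_artery", V0),
        propertyInstance("wk_outflow", "fluid.flow", "wk_artery"),
        propertyInstance("wk_sink_pressure", "fluid.force", "wk_sink"),
        propertyInstance("wk_R", "fluid.constitutive.resistance", "wk_artery", R),
        propertyInstance("wk_C", "fluid.constitutive.capacitance", "wk_artery", C)),
      dependencies = list(
        dependencyInstance("wk_dep_cap", "capacitive",
                           list(force_player_high = "wk_pressure", amount_player = "wk_volume",
                                constitutive = "wk_C")),
        dependencyInstance("wk_dep_res", "resistive",
                           list(flow_player = "wk_outflow", force_player_high = "wk_pressure",
                                force_player_low = "wk_sink_pressure", constitutive = "wk_R")),
        dependencyInstance("wk_dep_in", "boundary_flow",
                           list(target_player = "wk_volume", flow_player = "wk_inflow")),
        dependencyInstance("wk_dep_out", "boundary_flow",
                           list(source_player = "wk_volume", flow_player = "wk_outflow"))),
      sources = list(sourceSpec("wk_inflow", "constant", level = Q0),
                     sourceSpec("wk_sink_pressure", "constant", level = 0)),
      metadata = list(name = "windkessel",
                      description = "Two-element fluid Windkessel: compliance + peripheral resistance"))
  },

  # Electrical LC oscillator: dq/dt = -i, dp/dt = q/C, i = p/L.
  lc_oscillator = function(L = 1, C = 1, q0 = 1) {
    if (L <= 0 || C <= 0) physdepStop("E_BAD_CONSTITUTIVE", "lc_oscillator requires L > 0 and C > 0")
    modelNetwork(
      entities = list(entityNode("lc_capacitor", "electrical", "Capacitor"),
                      entityNode("lc_inductor", "electrical", "Inductor")),
      properties = list(
        propertyInstance("lc_charge", "electrical.amount", "lc_capacitor", q0),
        propertyInstance("lc_cap_force", "electrical.force", "lc_capacitor"),
        propertyInstance("lc_current", "electrical.flow", "lc_inductor"),
        propertyInstance("lc_flux", "electrical.momentum", "lc_inductor", 0),
        propertyInstance("lc_L", "electrical.constitutive.inductance", "lc_inductor", L),
        propertyInstance("lc_C", "electrical.constitutive.capacitance", "lc_capacitor", C)),
      dependencies = list(
        dependencyInstance("lc_dep_cap", "capacitive",
                           list(force_player_high = "lc_cap_force", amount_player = "lc_charge",
                                constitutive = "lc_C")),
        dependencyInstance("lc_dep_ind", "inductive",
                           list(flow_player = "lc_current", momentum_player = "lc_flux",
                                constitutive = "lc_L")),
        dependencyInstance("lc_dep_bq", "boundary_flow",
                           list(source_player = "lc_charge", flow_player = "lc_current")),
        dependencyInstance("lc_dep_bp", "boundary_force",
                           list(momentum_player = "lc_flux", force_player_high = "lc_cap_force"))),
      metadata = list(name = "lc_oscillator",
                      description = "Undamped LC oscillator: capacitive + inductive storage"))
  },

  # Reversible A <=> B with two boundary flows sharing one flux.
  mass_action_pair = function(k_f = 2, k_r = 1, A0 = 1, B0 = 2) {
    if (k_f <= 0 || k_r < 0) physdepStop("E_BAD_CONSTITUTIVE", "mass_action_pair requires k_f > 0, k_r >= 0")
    ks <- list(propertyInstance("ma_kf", "chemical.constitutive.rate_constant", "ma_reaction_site", k_f))
    bind <- list(flow_player = "ma_flux", source_player = "ma_A", target_player = "ma_B",
                 constitutive = "ma_kf")
    if (k_r > 0) {
      ks <- c(ks, list(propertyInstance("ma_kr", "chemical.constitutive.rate_constant",
                                        "ma_reaction_site", k_r)))
      bind$constitutive <- c("ma_kf", "ma_kr")
    }
    modelNetwork(
      entities = list(entityNode("ma_pool_A", "chemical", "Species A pool"),
                      entityNode("ma_pool_B", "chemical", "Species B pool"),
                      entityNode("ma_reaction_site", "chemical", "Reaction compartment")),
      processes = list(processNode("ma_reaction", c("ma_pool_A", "ma_pool_B"), "A <=> B")),
      properties = c(list(
        propertyInstance("ma_A", "chemical.amount", "ma_pool_A", A0),
        propertyInstance("ma_B", "chemical.amount", "ma_pool_B", B0),
        propertyInstance("ma_flux", "chemical.flow", "ma_reaction")), ks),
      dependencies = list(
        dependencyInstance("ma_dep_rate", "mass_action", bind),
        dependencyInstance("ma_dep_bA", "boundary_flow",
                           list(source_player = "ma_A", flow_player = "ma_flux")),
        dependencyInstance("ma_dep_bB", "boundary_flow",
                           list(target_player = "ma_B", flow_player = "ma_flux"))),
      metadata = list(name = "mass_action_pair",
                      description = "Reversible mass-action pair A <=> B"))
  },

  # Chemical potential source drives a mechanical resistive load through a
  # chemo-mechanical transducer (algebraic, power-conserving).
  chemo_mech_transducer = function(m = 0.5, mu0 = 1, Rload = 1) {
    if (m == 0 || Rload <= 0) physdepStop("E_BAD_CONSTITUTIVE", "transducer requires m != 0, Rload > 0")
    if (m < 0) physdepStop("E_BAD_CONSTITUTIVE", "modulus must be > 0")
    modelNetwork(
      entities = list(entityNode("cm_fuel", "chemical", "Fuel pool (e.g. ATP)"),
                      entityNode("cm_motor", "mechanical", "Molecular motor"),
                      entityNode("cm_load", "mechanical", "Viscous load")),
      properties = list(
        propertyInstance("cm_chem_potential", "chemical.force", "cm_fuel"),
        propertyInstance("cm_chem_flux", "chemical.flow", "cm_fuel"),
        propertyInstance("cm_mech_force", "mechanical.force", "cm_motor"),
        propertyInstance("cm_velocity", "mechanical.flow", "cm_motor"),
        propertyInstance("cm_ground_force", "mechanical.force", "cm_load"),
        propertyInstance("cm_modulus", "mechanical.constitutive.modulus", "cm_motor", m),
        propertyInstance("cm_Rload", "mechanical.constitutive.resistance", "cm_load", Rload)),
      dependencies = list(
        dependencyInstance("cm_dep_trans", "transducer",
                           list(force_player_1 = "cm_chem_potential", flow_player_1 = "cm_chem_flux",
                                force_player_2 = "cm_mech_force", flow_player_2 = "cm_velocity",
                                constitutive = "cm_modulus")),
        dependencyInstance("cm_dep_load", "resistive",
                           list(flow_player = "cm_velocity", force_player_high = "cm_mech_force",
                                force_player_low = "cm_ground_force", constitutive = "cm_Rload"))),
      sources = list(sourceSpec("cm_chem_potential", "constant", level = mu0),
                     sourceSpec("cm_ground_force", "constant", level = 0)),
      metadata = list(name = "chemo_mech_transducer",
                      description = "Chemo-mechanical transducer driving a viscous load"))
  },

  # Baroreflex as a transactor: aortic pressure proportionally (c < 0)
  # controls a cardiac rate property.
  baroreflex_toy = function(c = -0.5, P0 = 1) {
    modelNetwork(
      entities = list(entityNode("baro_aorta", "fluid", "Aortic segment"),
                      entityNode("baro_heart", "fluid", "Heart (pump rate)")),
      properties = list(
        propertyInstance("baro_pressure", "fluid.force", "baro_aorta"),
        propertyInstance("baro_heart_rate", "fluid.flow", "baro_heart"),
        propertyInstance("baro_coeff", "fluid.constitutive.coefficient", "baro_heart", c)),
      dependencies = list(
        dependencyInstance("baro_dep", "transactor",
                           list(source_player = "baro_pressure", target_player = "baro_heart_rate",
                                constitutive = "baro_coeff"))),
      sources = list(sourceSpec("baro_pressure", "constant", level = P0)),
      metadata = list(name = "baroreflex_toy",
                      description = "Baroreceptor reflex toy: negative proportional transactor"))
  },

  # Whole volume as the sum of part volumes (purely algebraic).
  multiscale_sum = function(parts = c(1, 2, 3)) {
    if (length(parts) < 1L) physdepStop("E_MISSING_ROLE", "multiscale_sum requires at least one part")
    n <- length(parts)
    segIds <- sprintf("ms_segment_%d", seq_len(n))
    volIds <- sprintf("ms_vol_%d", seq_len(n))
    modelNetwork(
      entities = c(list(entityNode("ms_organ", "fluid", "Whole organ")),
                   lapply(seq_len(n), function(i)
                     entityNode(segIds[i], "fluid", sprintf("Segment %d", i), partOf = "ms_organ"))),
      properties = c(list(propertyInstance("ms_total_volume", "fluid.amount", "ms_organ")),
                     lapply(seq_len(n), function(i)
                       propertyInstance(volIds[i], "fluid.amount", segIds[i], parts[i]))),
      dependencies = list(
        dependencyInstance("ms_dep_sum", "summation",
                           list(whole_player = "ms_total_volume", part_player = volIds))),
      metadata = list(name = "multiscale_sum",
                      description = "Organ volume as the sum of its segment volumes"))
  }
)

#' Names of the built-in fixtures
#' @return Character vector.
#' @export
fixtureNames <- function() names(.fixtureBuilders)

#' Build a canonical fixture network
#'
#' Fully parameterized stand-ins for external data: an RC charging circuit, a
#' two-element Windkessel, an LC oscillator, a reversible mass-action pair, a
#' chemo-mechanical transducer, a baroreflex transactor toy, and a
#' part-volume summation. Every fixture passes [validateNetwork()] with zero
#' errors at its default parameters.
#'
#' @param name One of [fixtureNames()].
#' @param params Named list overriding the fixture's default parameters.
#' @return A [ModelNetwork-class].
#' @examples
#' makeFixture("windkessel", list(R = 2, Q0 = 0.5))
#' @export
makeFixture <- function(name, params = list()) {
  b <- .fixtureBuilders[[name]]
  if (is.null(b)) physdepStop("E_SCHEMA", sprintf("unknown fixture '%s'", name))
  do.call(b, params)
}

#' Random single-domain capacitor-resistor tree network
#'
#' Generates `nStorage` capacitive storage nodes joined by a random spanning
#' tree of resistive connections, `nResistive` extra resistive links, and one
#' constant force source feeding node 1. Loop-free under storage causality by
#' construction (every resistive flow is driven by capacitive forces), hence
#' always compilable; deterministic per seed.
#'
#' @param seed Integer RNG seed.
#' @param nStorage Number of storage nodes, >= 1.
#' @param nResistive Number of extra resistive links beyond the spanning tree.
#' @return A [ModelNetwork-class].
#' @export
randomizedNetwork <- function(seed, nStorage = 3, nResistive = 2) {
  if (nStorage < 1L) physdepStop("E_BAD_VALUE", "nStorage must be >= 1")
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  ents <- list(); props <- list(); deps <- list()
  for (i in seq_len(nStorage)) {
    ents[[i]] <- entityNode(sprintf("rn_node_%02d", i), "electrical", sprintf("Storage node %d", i))
    props <- c(props, list(
      propertyInstance(sprintf("rn_charge_%02d", i), "electrical.amount",
                       sprintf("rn_node_%02d", i), stats::runif(1, 0.5, 1.5)),
      propertyInstance(sprintf("rn_force_%02d", i), "electrical.force", sprintf("rn_node_%02d", i)),
      propertyInstance(sprintf("rn_C_%02d", i), "electrical.constitutive.capacitance",
                       sprintf("rn_node_%02d", i), stats::runif(1, 0.5, 2))))
    deps <- c(deps, list(dependencyInstance(
      sprintf("rn_dep_cap_%02d", i), "capacitive",
      list(force_player_high = sprintf("rn_force_%02d", i),
           amount_player = sprintf("rn_charge_%02d", i),
           constitutive = sprintf("rn_C_%02d", i)))))
  }
  link <- function(tag, i, j) {
    flowId <- sprintf("rn_flow_%s", tag); rId <- sprintf("rn_R_%s", tag)
    props <<- c(props, list(
      propertyInstance(flowId, "electrical.flow", sprintf("rn_node_%02d", i)),
      propertyInstance(rId, "electrical.constitutive.resistance",
                       sprintf("rn_node_%02d", i), stats::runif(1, 0.5, 2))))
    deps <<- c(deps, list(
      dependencyInstance(sprintf("rn_dep_res_%s", tag), "resistive",
                         list(flow_player = flowId,
                              force_player_high = sprintf("rn_force_%02d", i),
                              force_player_low = sprintf("rn_force_%02d", j),
                              constitutive = rId)),
      dependencyInstance(sprintf("rn_dep_bnd_%s", tag), "boundary_flow",
                         list(source_player = sprintf("rn_charge_%02d", i),
                              target_player = sprintf("rn_charge_%02d", j),
                              flow_player = flowId))))
  }
  if (nStorage > 1L)
    for (j in 2:nStorage) link(sprintf("t%02d", j), sample.int(j - 1L, 1L), j)
  if (nResistive > 0L)
    for (k in seq_len(nResistive)) {
      i <- sample.int(nStorage, 1L)
      j <- if (nStorage > 1L) sample(setdiff(seq_len(nStorage), i), 1L) else i
      if (i != j) link(sprintf("x%02d", k), i, j)
    }
  # source feed into node 1 through its own resistance
  props <- c(props, list(
    propertyInstance("rn_src_force", "electrical.force", "rn_node_01"),
    propertyInstance("rn_flow_src", "electrical.flow", "rn_node_01"),
    propertyInstance("rn_R_src", "electrical.constitutive.resistance", "rn_node_01",
                     stats::runif(1, 0.5, 2))))
  deps <- c(deps, list(
    dependencyInstance("rn_dep_res_src", "resistive",
                       list(flow_player = "rn_flow_src", force_player_high = "rn_src_force",
                            force_player_low = "rn_force_01", constitutive = "rn_R_src")),
    dependencyInstance("rn_dep_bnd_src", "boundary_flow",
                       list(target_player = "rn_charge_01", flow_player = "rn_flow_src"))))
  modelNetwork(ents, list(), props, deps,
               sources = list(sourceSpec("rn_src_force", "constant", level = stats::runif(1, 0.5, 2))),
               metadata = list(name = sprintf("randomized_%d", seed),
                               description = sprintf("Random capacitor-resistor tree (seed %d)", seed)))
}
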