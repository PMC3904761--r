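test_that("state identification picks boundary-driven amounts and momenta", {
  expect_equal(identifyStates(makeFixture("rc_circuit")), "rc_charge")
  expect_equal(identifyStates(makeFixture("lc_oscillator")), c("lc_charge", "lc_flux"))
  expect_equal(identifyStates(makeFixture("multiscale_sum")), character(0))

  net <- makeFixture("rc_circuit")
  net@properties[["rc_charge"]]@value <- NA_real_
  expect_error(identifyStates(net), class = "E_NO_INITIAL")
})

test_that("causality orients every dependency and flags over/under-determination", {
  net <- makeFixture("rc_circuit")
  ca <- assignCausality(net)
  expect_equal(unname(ca$outputs["rc_cap_force"]), "rc_dep_cap")
  expect_equal(unname(ca$outputs["rc_current"]), "rc_dep_res")
  expect_equal(ca$states, "rc_charge")

  # two resistive dependencies claiming the same flow property
  over <- net
  over@dependencies[["rc_dep_res2"]] <- dependencyInstance("rc_dep_res2", "resistive",
    list(flow_player = "rc_current", force_player_high = "rc_src_force",
         force_player_low = "rc_cap_force", constitutive = "rc_R"))
  err <- tryCatch(assignCausality(over), physdepError = function(e) e)
  expect_s3_class(err, "E_OVERDETERMINED")
  expect_equal(err$data$id, "rc_current")

  # force property with no provider
  under <- net
  under@properties[["rc_orphan"]] <- propertyInstance("rc_orphan", "electrical.force", "rc_capacitor")
  err <- tryCatch(assignCausality(under), physdepError = function(e) e)
  expect_s3_class(err, "E_UNDERDETERMINED")
  expect_equal(err$data$id, "rc_orphan")

  # prescribed constants: valueless uncomputed amounts fail, valued ones pass
  expect_silent(assignCausality(makeFixture("multiscale_sum")))
})

test_that("the schedule is a deterministic topological order", {
  net <- makeFixture("rc_circuit")
  sched <- buildSchedule(net)
  expect_equal(nrow(sched), 2L)
  expect_lt(which(sched$dependency == "rc_dep_cap"), which(sched$dependency == "rc_dep_res"))
  expect_identical(buildSchedule(net), sched)

  # transducer splits into two causal steps around the load
  sched <- buildSchedule(makeFixture("chemo_mech_transducer"))
  expect_equal(sched$output,
               c("cm_mech_force", "cm_velocity", "cm_chem_flux"))
})

test_that("a feedback cycle with no storage node raises E_ALGEBRAIC_LOOP", {
  # resistive flow feeds back onto its own low force through a transactor:
  # no capacitor between them, so no causal order exists
  loop <- modelNetwork(
    entities = list(entityNode("lp_e", "electrical")),
    properties = list(
      propertyInstance("lp_src", "electrical.force", "lp_e"),
      propertyInstance("lp_f", "electrical.force", "lp_e"),
      propertyInstance("lp_i", "electrical.flow", "lp_e"),
      propertyInstance("lp_R", "electrical.constitutive.resistance", "lp_e", 1),
      propertyInstance("lp_c", "electrical.constitutive.coefficient", "lp_e", 1)),
    dependencies = list(
      dependencyInstance("lp_res", "resistive",
                         list(flow_player = "lp_i", force_player_high = "lp_src",
                              force_player_low = "lp_f", constitutive = "lp_R")),
      dependencyInstance("lp_tr", "transactor",
                         list(source_player = "lp_i", target_player = "lp_f",
                              constitutive = "lp_c"))),
    sources = list(sourceSpec("lp_src", "constant", level = 1)),
    metadata = list(name = "loop", description = ""))
  expect_equal(nrow(errorsOf(loop)), 0L)
  err <- tryCatch(buildSchedule(loop), physdepError = function(e) e)
  expect_s3_class(err, "E_ALGEBRAIC_LOOP")
  expect_setequal(err$data$dependencies, c("lp_res", "lp_tr"))
})

test_that("compiled RC right-hand side equals the hand-written ODE", {
  R <- 1; C <- 1; E0 <- 1
  sys <- compileNetwork(makeFixture("rc_circuit", list(R = R, C = C, E0 = E0, q0 = 0)))
  e <- evalRHS(sys, 0, c(rc_charge = 0))
  expect_equal(unname(e$deriv), 1)   # (E0 - 0/C)/R

  R <- 2; C <- 0.5; E0 <- 1.7
  sys <- compileNetwork(makeFixture("rc_circuit", list(R = R, C = C, E0 = E0, q0 = 0)))
  handRHS <- function(q) (E0 - q / C) / R
  set.seed(91)
  for (q in runif(100, -3, 3))
    expect_equal(unname(evalRHS(sys, 0, c(rc_charge = q))$deriv), handRHS(q),
                 tolerance = 1e-14)
})

test_that("compiled LC right-hand side matches the hand-derived pair", {
  sys <- compileNetwork(makeFixture("lc_oscillator", list(L = 1, C = 1, q0 = 1)))
  e <- evalRHS(sys, 0, c(lc_charge = 1, lc_flux = 0))
  expect_equal(e$deriv, c(lc_charge = 0, lc_flux = 1))  # dq/dt = -i = 0, dp/dt = q/C
})

test_that("compilation is deterministic and the equation listing is complete", {
  s1 <- compileNetwork(makeFixture("windkessel"))
  s2 <- compileNetwork(makeFixture("windkessel"))
  expect_identical(odeStates(s1), odeStates(s2))
  expect_identical(odeSchedule(s1), odeSchedule(s2))
  # schedule is a permutation of all algebraic dependencies
  alg <- Filter(function(d) !dependencyKind(d@kind)$boundary,
                networkDependencies(makeFixture("windkessel")))
  expect_setequal(odeSchedule(s1)$dependency, vapply(alg, function(d) d@id, ""))
  lst <- equationListing(s1)
  expect_true(any(grepl("^d\\(wk_volume\\)/dt", lst)))
  expect_length(lst, 1L + nrow(odeSchedule(s1)))
})

test_that("compiling an invalid network reports the validation failure", {
  net <- makeFixture("rc_circuit")
  net@properties[["rc_R"]]@value <- -1
  expect_error(compileNetwork(net), class = "E_INVALID_NETWORK")
})

test_that("mass-action compilation guards against negative amounts", {
  net <- makeFixture("mass_action_pair", list(k_f = 1, k_r = 0.5, A0 = -1, B0 = 1))
  sys <- compileNetwork(net)
  expect_error(evalRHS(sys, 0, c(ma_A = -1, ma_B = 1)), class = "E_NEGATIVE_STATE")
})

test_that("Michaelis-Menten and spatial dependencies compile and evaluate", {
  net <- modelNetwork(
    entities = list(entityNode("mm_cell", "chemical"), entityNode("mm_fiber", "mechanical")),
    properties = list(
      propertyInstance("mm_S", "chemical.amount", "mm_cell", 2),
      propertyInstance("mm_v", "chemical.flow", "mm_cell"),
      propertyInstance("mm_len", "mechanical.amount", "mm_fiber")),
    dependencies = list(
      dependencyInstance("mm_rate", "michaelis_menten",
                         list(flow_player = "mm_v", amount_player = "mm_S"),
                         params = c(Vmax = 3, Km = 1)),
      dependencyInstance("mm_geom", "spatial",
                         list(source_player = "mm_S", target_player = "mm_len"),
                         params = c(a = 2, b = 0.5)),
      dependencyInstance("mm_drain", "boundary_flow",
                         list(source_player = "mm_S", flow_player = "mm_v"))),
    metadata = list(name = "mm", description = ""))
  expect_equal(nrow(errorsOf(net)), 0L)
  sys <- compileNetwork(net)
  e <- evalRHS(sys, 0, c(mm_S = 2))
  expect_equal(e$values[["mm_v"]], 3 * 2 / (1 + 2))
  expect_equal(e$values[["mm_len"]], 2 * sqrt(2))
  expect_equal(unname(e$deriv), -2)
})
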