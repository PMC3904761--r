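test_that("assembly resolves references and counts fixture components", {
  net <- makeFixture("rc_circuit")
  expect_length(networkEntities(net), 3L)
  expect_length(networkProcesses(net), 1L)
  expect_length(networkProperties(net), 6L)
  expect_length(networkDependencies(net), 3L)
  expect_length(networkSources(net), 1L)

  spec <- list(
    entities = list(list(id = "e1", domain = "electrical")),
    properties = list(list(id = "p1", class = "electrical.force", bearer = "e1")),
    dependencies = list(list(id = "d1", kind = "transactor",
                             bindings = list(list(role = "source_player", property = "p1"),
                                             list(role = "target_player", property = "p99")))))
  err <- tryCatch(assembleNetwork(spec), physdepError = function(e) e)
  expect_s3_class(err, "E_UNRESOLVED_REF")
  expect_equal(err$data$id, "p99")

  dup <- list(entities = list(list(id = "e1", domain = "electrical"),
                              list(id = "e1", domain = "fluid")))
  expect_error(assembleNetwork(dup), class = "E_DUPLICATE_ID")

  empty <- assembleNetwork(list())
  expect_s4_class(empty, "ModelNetwork")
  expect_length(networkProperties(empty), 0L)
  expect_equal(nrow(validateNetwork(empty)), 0L)
})

test_that("unknown dependency kinds are rejected at assembly", {
  spec <- list(entities = list(list(id = "e1", domain = "electrical")),
               properties = list(list(id = "p1", class = "electrical.force", bearer = "e1")),
               dependencies = list(list(id = "d1", kind = "frobnicate", bindings = list())))
  expect_error(assembleNetwork(spec), class = "E_SCHEMA")
})

test_that("signature violations are each detected on constructed counterexamples", {
  base <- function(deps, props = list(), sources = list()) {
    modelNetwork(
      entities = list(entityNode("ex_e", "electrical"), entityNode("ex_f", "fluid")),
      properties = c(list(
        propertyInstance("ex_flow", "electrical.flow", "ex_e"),
        propertyInstance("ex_fhi", "electrical.force", "ex_e"),
        propertyInstance("ex_flo", "electrical.force", "ex_e"),
        propertyInstance("ex_amt", "electrical.amount", "ex_e", 0),
        propertyInstance("ex_fluid_flow", "fluid.flow", "ex_f"),
        propertyInstance("ex_R", "electrical.constitutive.resistance", "ex_e", 2)), props),
      dependencies = deps, sources = sources,
      metadata = list(name = "counterexample", description = ""))
  }
  # missing role
  net <- base(list(dependencyInstance("ex_d", "resistive",
                                      list(flow_player = "ex_flow", constitutive = "ex_R"))))
  errs <- errorsOf(net)
  expect_true(any(errs$code == "E_MISSING_ROLE" &
                  grepl("force_player_high", errs$message)))
  # wrong category
  net <- base(list(dependencyInstance("ex_d", "resistive",
                                      list(flow_player = "ex_amt", force_player_high = "ex_fhi",
                                           force_player_low = "ex_flo", constitutive = "ex_R"))))
  expect_true(any(errorsOf(net)$code == "E_WRONG_CATEGORY"))
  # domain mismatch: fluid flow player, electrical force players
  net <- base(list(dependencyInstance("ex_d", "resistive",
                                      list(flow_player = "ex_fluid_flow", force_player_high = "ex_fhi",
                                           force_player_low = "ex_flo", constitutive = "ex_R"))))
  expect_true(any(errorsOf(net)$code == "E_DOMAIN_MISMATCH"))
  # non-positive constitutive
  net <- base(list(dependencyInstance("ex_d", "resistive",
                                      list(flow_player = "ex_flow", force_player_high = "ex_fhi",
                                           force_player_low = "ex_flo", constitutive = "ex_Rbad"))),
              props = list(propertyInstance("ex_Rbad", "electrical.constitutive.resistance", "ex_e", -1)))
  expect_true(any(errorsOf(net)$code == "E_BAD_CONSTITUTIVE"))
  # undeclared role
  net <- base(list(dependencyInstance("ex_d", "capacitive",
                                      list(force_player_high = "ex_fhi", amount_player = "ex_amt",
                                           whole_player = "ex_amt", constitutive = "ex_C"))),
              props = list(propertyInstance("ex_C", "electrical.constitutive.capacitance", "ex_e", 1)))
  expect_true(any(errorsOf(net)$code == "E_UNKNOWN_ROLE"))
  # source must drive a force or flow
  net <- base(list(), sources = list(sourceSpec("ex_amt", "constant", level = 1)))
  expect_true(any(errorsOf(net)$code == "E_BAD_SOURCE"))
  # boundary-driven state without an initial value
  net <- base(list(dependencyInstance("ex_b", "boundary_flow",
                                      list(target_player = "ex_amt2", flow_player = "ex_flow"))),
              props = list(propertyInstance("ex_amt2", "electrical.amount", "ex_e")))
  expect_true(any(errorsOf(net)$code == "E_NO_INITIAL"))
})

test_that("transducers must span two domains; transactor mismatch is a warning", {
  net <- makeFixture("chemo_mech_transducer")
  expect_equal(nrow(errorsOf(net)), 0L)

  # same-domain 'transducer' is an error
  bad <- modelNetwork(
    entities = list(entityNode("td_e", "mechanical")),
    properties = list(
      propertyInstance("td_f1", "mechanical.force", "td_e"),
      propertyInstance("td_q1", "mechanical.flow", "td_e"),
      propertyInstance("td_f2", "mechanical.force", "td_e"),
      propertyInstance("td_q2", "mechanical.flow", "td_e"),
      propertyInstance("td_m", "mechanical.constitutive.modulus", "td_e", 2)),
    dependencies = list(dependencyInstance("td_d", "transducer",
      list(force_player_1 = "td_f1", flow_player_1 = "td_q1",
           force_player_2 = "td_f2", flow_player_2 = "td_q2", constitutive = "td_m"))),
    metadata = list(name = "bad_transducer", description = ""))
  expect_true(any(errorsOf(bad)$code == "E_DOMAIN_MISMATCH"))

  # cross-domain transactor: warning only
  wild <- modelNetwork(
    entities = list(entityNode("wa_a", "fluid"), entityNode("wa_b", "mechanical")),
    properties = list(
      propertyInstance("wa_p", "fluid.force", "wa_a"),
      propertyInstance("wa_v", "mechanical.flow", "wa_b"),
      propertyInstance("wa_c", "fluid.constitutive.coefficient", "wa_a", -1)),
    dependencies = list(dependencyInstance("wa_d", "transactor",
      list(source_player = "wa_p", target_player = "wa_v", constitutive = "wa_c"))),
    sources = list(sourceSpec("wa_p", "constant", level = 1)),
    metadata = list(name = "wildcard", description = ""))
  rep <- validateNetwork(wild)
  expect_equal(sum(rep$level == "error"), 0L)
  expect_true(any(rep$level == "warning" & rep$code == "E_DOMAIN_MISMATCH"))
})

test_that("validation is idempotent, deterministic, and ordered by subject", {
  net <- makeFixture("rc_circuit")
  net@properties[["rc_R"]]@value <- -2
  r1 <- validateNetwork(net)
  r2 <- validateNetwork(net)
  expect_identical(r1, r2)
  expect_equal(r1$subject, sort(r1$subject))
})

test_that("influence edges carry the causal signs of each law", {
  edges <- influenceEdges(makeFixture("rc_circuit"))
  has <- function(from, to, sign)
    any(edges$from == from & edges$to == to & edges$sign == sign)
  expect_true(has("rc_charge", "rc_cap_force", "+"))
  expect_true(has("rc_src_force", "rc_current", "+"))
  expect_true(has("rc_cap_force", "rc_current", "-"))
  expect_true(has("rc_current", "rc_charge", "+"))

  edges <- influenceEdges(makeFixture("baroreflex_toy"))
  expect_true(has("baro_pressure", "baro_heart_rate", "-"))

  edges <- influenceEdges(makeFixture("multiscale_sum"))
  expect_equal(sum(edges$to == "ms_total_volume" & edges$sign == "+"), 3L)

  # boundary flow: + into target, - out of source
  edges <- influenceEdges(makeTwoCompartment())
  expect_true(has("tc_flow", "tc_q2", "+"))
  expect_true(has("tc_flow", "tc_q1", "-"))

  expect_error(influenceEdges(modelNetwork(
    entities = list(entityNode("x", "electrical")),
    properties = list(propertyInstance("p", "electrical.force", "x")),
    metadata = list(name = "m", description = ""))), class = "E_NOT_COMPILED")
})
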