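test_that("constant inflow integrates exactly; bad steps are rejected", {
  net <- makeFixture("windkessel", list(R = 1e9, C = 1, Q0 = 1, V0 = 0))  # drain ~ off
  traj <- integrateODE(compileNetwork(net), tEnd = 2, dt = 0.01)
  v <- trajectoryValues(traj)
  expect_equal(unname(v[nrow(v), "wk_volume"]), 2, tolerance = 1e-8)
  sys <- compileNetwork(makeFixture("rc_circuit"))
  expect_error(integrateODE(sys, tEnd = 1, dt = 0), class = "E_BAD_VALUE")
  expect_error(integrateODE(sys, tEnd = -1, dt = 0.1), class = "E_BAD_VALUE")
})

test_that("RC trajectory matches the closed-form exponential to 1e-6", {
  R <- 2; C <- 0.5; E0 <- 1
  sys <- compileNetwork(makeFixture("rc_circuit", list(R = R, C = C, E0 = E0, q0 = 0)))
  traj <- integrateODE(sys, tEnd = 5, dt = 1e-3)
  t <- trajectoryTimes(traj)
  force <- trajectoryValues(traj)[, "rc_cap_force"]
  exact <- rcClosedForm(t, R, C, E0) / C
  expect_lt(max(abs(force - exact)), 1e-6)
  expect_equal(unname(force[which.min(abs(t - 1))]), 1 - exp(-1), tolerance = 1e-6)
})

test_that("halving dt cuts the RC error about sixteen-fold (4th order)", {
  R <- 2; C <- 0.5; E0 <- 1
  sys <- compileNetwork(makeFixture("rc_circuit", list(R = R, C = C, E0 = E0, q0 = 0)))
  errAt <- function(dt) {
    traj <- integrateODE(sys, tEnd = 1, dt = dt)
    q <- trajectoryValues(traj)[, "rc_charge"]
    abs(q[length(q)] - rcClosedForm(1, R, C, E0))
  }
  errs <- vapply(c(0.1, 0.05, 0.025, 0.0125), errAt, 0)
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 12 & ratios < 20))
})

test_that("integration against an independent adaptive solver agrees", {
  R <- 2; C <- 0.5; E0 <- 1
  sys <- compileNetwork(makeFixture("rc_circuit", list(R = R, C = C, E0 = E0, q0 = 0)))
  mine <- integrateODE(sys, tEnd = 3, dt = 1e-3)
  ref <- deSolve::lsoda(c(q = 0), times = seq(0, 3, by = 0.5),
                        func = function(t, y, p) list((E0 - y / C) / R),
                        rtol = 1e-10, atol = 1e-12)
  atRef <- trajectoryValues(mine)[trajectoryTimes(mine) %in% ref[, "time"], "rc_charge"]
  expect_equal(unname(atRef), unname(ref[, "q"]), tolerance = 1e-7)
})

test_that("closed exchange conserves total amount to machine precision", {
  sys <- compileNetwork(makeTwoCompartment())
  traj <- integrateODE(sys, tEnd = 10, dt = 1e-3)   # 1e4 steps
  v <- trajectoryValues(traj)
  total <- v[, "tc_q1"] + v[, "tc_q2"]
  expect_lt(max(abs(total - total[1])) / total[1], 1e-12)
  # and the derivative sum is analytically zero at every recorded point
  e <- evalRHS(sys, 0, c(tc_q1 = 1.2, tc_q2 = 0.3))
  expect_identical(sum(e$deriv), 0)
})

test_that("LC oscillator conserves energy and oscillates at 2*pi*sqrt(LC)", {
  L <- 1; C <- 1
  sys <- compileNetwork(makeFixture("lc_oscillator", list(L = L, C = C, q0 = 1)))
  period <- 2 * pi * sqrt(L * C)
  traj <- integrateODE(sys, tEnd = 10 * period, dt = period / 1000)
  v <- trajectoryValues(traj)
  energy <- v[, "lc_charge"]^2 / (2 * C) + v[, "lc_flux"]^2 / (2 * L)
  expect_lt(max(abs(energy - energy[1])) / energy[1], 1e-6)
  crossings <- zeroCrossings(trajectoryTimes(traj), v[, "lc_charge"])
  expect_gte(length(crossings), 9L)
  expect_lt(max(abs(diff(crossings) - period)) / period, 1e-3)
})

test_that("steady states: Windkessel relaxes to Q0*R, RC to the source force", {
  R <- 1.5; C <- 2; Q0 <- 0.8
  ss <- steadyState(compileNetwork(makeFixture("windkessel", list(R = R, C = C, Q0 = Q0))))
  expect_equal(ss$values[["wk_pressure"]], Q0 * R, tolerance = 1e-8)
  expect_equal(ss$values[["wk_volume"]], C * Q0 * R, tolerance = 1e-8)

  ss <- steadyState(compileNetwork(makeFixture("rc_circuit", list(R = 2, C = 0.5, E0 = 1.3, q0 = 0))))
  expect_equal(ss$values[["rc_cap_force"]], 1.3, tolerance = 1e-8)
  expect_equal(ss$values[["rc_current"]], 0, tolerance = 1e-8)

  expect_error(steadyState(compileNetwork(makeFixture("lc_oscillator")), tMax = 15),
               class = "E_NO_STEADY_STATE")
})

test_that("constant force on a mass gives velocity slope F/m exactly", {
  F <- 2; m <- 0.5
  sys <- compileNetwork(makeNewtonRig(F, m))
  traj <- integrateODE(sys, tEnd = 1, dt = 0.05)
  t <- trajectoryTimes(traj)
  vel <- trajectoryValues(traj)[, "nw_velocity"]
  expect_lt(max(abs(vel - (F / m) * t)), 1e-13)  # RK4 on constant rhs: rounding only
})

test_that("trajectories export as full-precision CSV", {
  sys <- compileNetwork(makeFixture("rc_circuit"))
  traj <- integrateODE(sys, tEnd = 1, dt = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrajectoryCSV(traj, path)
  lines <- readLines(path)
  expect_equal(length(lines), 12L)  # header + 11 grid points
  expect_match(lines[1], "^time,")
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$time, trajectoryTimes(traj))
  expect_equal(back$rc_charge, unname(trajectoryValues(traj)[, "rc_charge"]))
  df <- as.data.frame(traj)
  expect_equal(colnames(df)[1], "time")
  expect_equal(nrow(df), 11L)
})
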