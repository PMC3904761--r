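# Fixed-step classical Runge-Kutta integration of compiled systems, steady
# state location, and trajectory export.

#' Trajectory: property values over a time grid
#'
#' @slot time Strictly increasing numeric grid (s).
#' @slot values Numeric matrix, one row per grid point, one column per
#'   property id (states and algebraic properties alike).
#' @export
setClass("Trajectory",
         representation(time = "numeric", values = "matrix"),
         validity = function(object) {
           if (length(object@time) < 2L) return("time grid must have length >= 2")
           if (any(diff(object@time) <= 0)) return("time grid must be strictly increasing")
           if (nrow(object@values) != length(object@time)) return("values/time size mismatch")
           TRUE
         })

#' @rdname integrateODE
#' @param traj A [Trajectory-class].
#' @export
trajectoryTimes <- function(traj) traj@time

#' @rdname integrateODE
#' @export
trajectoryValues <- function(traj) traj@values

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d points over [%g, %g], %d properties\n",
              length(object@time), object@time[1], object@time[length(object@time)],
              ncol(object@values)))
})

#' Integrate a compiled system with fixed-step classical RK4
#'
#' Deterministic, bit-stable fixed-step 4th-order Runge-Kutta from `t = 0` to
#' `tEnd`. States and every algebraic property are recorded at every grid
#' point, so forces and flows -- the physiologically named quantities -- are
#' directly inspectable.
#'
#' @param sys An [ODESystem-class].
#' @param tEnd End time, > 0.
#' @param dt Step size, > 0.
#' @return A [Trajectory-class] with `round(tEnd/dt) + 1` grid points.
#' @examples
#' traj <- integrateODE(compileNetwork(makeFixture("rc_circuit")), tEnd = 1, dt = 0.01)
#' utils::head(as.data.frame(traj))
#' @export
integrateODE <- function(sys, tEnd, dt) {
  if (!is.numeric(tEnd) || tEnd <= 0) physdepStop("E_BAD_VALUE", "tEnd must be > 0")
  if (!is.numeric(dt) || dt <= 0) physdepStop("E_BAD_VALUE", "dt must be > 0")
  n <- round(tEnd / dt)
  time <- seq(0, by = dt, length.out = n + 1L)
  y <- sys@init
  propIds <- names(sys@internals$base)
  vals <- matrix(NA_real_, nrow = n + 1L, ncol = length(propIds),
                 dimnames = list(NULL, propIds))
  f <- function(t, y) evalRHS(sys, t, y)
  for (i in seq_len(n + 1L)) {
    t <- time[i]
    e1 <- f(t, y)
    vals[i, ] <- e1$values
    if (any(!is.finite(e1$values[!is.na(e1$values)])))
      physdepStop("E_DIVERGED", sprintf("non-finite value at t = %g", t), t = t)
    if (i > n) break
    if (length(y)) {
      k1 <- e1$deriv
      k2 <- f(t + dt / 2, y + dt / 2 * k1)$deriv
      k3 <- f(t + dt / 2, y + dt / 2 * k2)$deriv
      k4 <- f(t + dt, y + dt * k3)$deriv
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(y)))
        physdepStop("E_DIVERGED", sprintf("state diverged at t = %g", t + dt), t = t + dt)
    }
  }
  new("Trajectory", time = time, values = vals)
}

#' @rdname integrateODE
#' @param x A [Trajectory-class].
#' @param row.names,optional,... Passed through (see [base::as.data.frame]).
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x@time, x@values, check.names = FALSE)
}
setMethod("as.data.frame", "Trajectory", as.data.frame.Trajectory)

#' Write a trajectory as CSV
#'
#' First column `time`, one column per property id, header row, full double
#' precision (`%.17g`).
#'
#' @param traj A [Trajectory-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- as.data.frame(traj)
  header <- paste(colnames(df), collapse = ",")
  body <- apply(df, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Locate a steady state by relaxation
#'
#' Integrates (RK4, fixed step) until the max-norm of the state derivative
#' drops below `tol`. Only defined for constant sources. Purely algebraic
#' systems (no states) are at steady state immediately.
#'
#' @param sys An [ODESystem-class].
#' @param tMax Give up after this much model time (`E_NO_STEADY_STATE`, as for
#'   an undamped oscillator).
#' @param dt Integration step.
#' @param tol Convergence tolerance on `max(abs(d state/dt))`.
#' @return List with `state` (named numeric), `values` (all property values),
#'   and `t` (time of convergence).
#' @examples
#' ss <- steadyState(compileNetwork(makeFixture("windkessel")))
#' ss$values[["wk_pressure"]]   # Q0 * R
#' @export
steadyState <- function(sys, tMax = 200, dt = 0.01, tol = 1e-12) {
  for (s in sys@internals$sources)
    if (s@waveform != "constant")
      physdepStop("E_BAD_SOURCE",
                  sprintf("steadyState requires constant sources; '%s' is %s", s@property, s@waveform))
  y <- sys@init
  t <- 0
  chunk <- 100L
  repeat {
    e <- evalRHS(sys, t, y)
    if (!length(y) || max(abs(e$deriv)) < tol)
      return(list(state = y, values = e$values, t = t))
    if (t >= tMax)
      physdepStop("E_NO_STEADY_STATE",
                  sprintf("no steady state within tMax = %g (max |d/dt| = %g)", tMax, max(abs(e$deriv))))
    f <- function(tt, yy) evalRHS(sys, tt, yy)$deriv
    for (i in seq_len(chunk)) {
      k1 <- f(t, y)
      k2 <- f(t + dt / 2, y + dt / 2 * k1)
      k3 <- f(t + dt / 2, y + dt / 2 * k2)
      k4 <- f(t + dt, y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + dt
      if (any(!is.finite(y)))
        physdepStop("E_DIVERGED", sprintf("state diverged at t = %g", t), t = t)
    }
  }
}
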