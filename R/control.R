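#' Controlled tangent field for apical tip steering (planar)
#'
#' Standalone 2D formulation of tip steering as an optimal-control problem:
#' an organ of fixed length carries a tangent field
#' `T(s, t) = (sin theta, cos theta)` (angle `theta` measured from the
#' stimulus direction), and a control `u(t)` applied at the tip drives every
#' point as `dT(s, t)/dt = s * u(t)` — apical sensing broadcast along the
#' organ. Growth is not modelled explicitly here and the arc grid is fixed.
#'
#' @param theta Numeric vector: the angle field on the arc grid
#'   `s = 0, ds, ..., L`, including the clamped base entry at `s = 0`.
#' @param ds Arc-grid spacing (> 0).
#' @param n_hat Unit 2-vector, stimulus direction.
#' @param beta Control gain (>= 0).
#' @param time Current time.
#' @return An object of class `control_state`.
#' @export
control_state <- function(theta, ds, n_hat = c(0, 1), beta = 1, time = 0) {
  stopifnot(ds > 0, beta >= 0, length(n_hat) == 2)
  n_hat <- as.numeric(n_hat)
  n_hat <- n_hat / sqrt(sum(n_hat^2))
  structure(list(theta = as.numeric(theta), ds = ds, n_hat = n_hat,
                 beta = beta, time = time),
            class = "control_state")
}

#' Tangent vectors of a control state
#'
#' `T(s) = sin(theta) * p + cos(theta) * n_hat` with `p` the in-plane
#' perpendicular of `n_hat`, so that `theta = 0` means alignment.
#'
#' @param state A [control_state()].
#' @return Matrix with one unit 2-vector row per grid point.
#' @export
control_tangents <- function(state) {
  p <- c(state$n_hat[2], -state$n_hat[1])
  cbind(sin(state$theta) * p[1] + cos(state$theta) * state$n_hat[1],
        sin(state$theta) * p[2] + cos(state$theta) * state$n_hat[2])
}

#' Optimal apical control input
#'
#' The zero-cost member of the optimal control family:
#' `u* = beta * T_perp(L) * (n_hat . T_perp(L))` with
#' `T_perp = (-T2, T1)`. The control is always admissible
#' (`n_hat . u* = beta (n_hat . T_perp)^2 >= 0`), avoiding the curling
#' dynamics of controls that push away from the stimulus, and vanishes
#' exactly at alignment.
#'
#' @param tip_tangent Unit 2-vector `T(L)`.
#' @param n_hat Unit 2-vector, stimulus direction.
#' @param beta Control gain (>= 0).
#' @return Numeric 2-vector.
#' @export
control_input <- function(tip_tangent, n_hat, beta = 1) {
  stopifnot(beta >= 0, abs(sum(tip_tangent^2) - 1) < 1e-8,
            abs(sum(n_hat^2) - 1) < 1e-8)
  t_perp <- c(-tip_tangent[2], tip_tangent[1])
  beta * sum(n_hat * t_perp) * t_perp
}

#' Advance the controlled tangent field one time step
#'
#' The vector dynamics `dT(s)/dt = s * u(t)` do not preserve unit tangents
#' under naive explicit stepping, so the equivalent angle form is integrated
#' instead: for the optimal control this is
#' `d theta(s) / dt = -s * beta * sin(theta(L))`,
#' which keeps every tangent exactly unit-norm (the geometric content of the
#' zero-cost condition). The clamped base (`s = 0`) never moves.
#'
#' @param state A [control_state()].
#' @param dt Time step (> 0).
#' @return The updated [control_state()].
#' @export
evolve_tangent <- function(state, dt) {
  stopifnot(inherits(state, "control_state"), dt > 0)
  n <- length(state$theta)
  s <- (seq_len(n) - 1) * state$ds
  theta_L <- state$theta[n]
  state$theta <- state$theta - dt * s * state$beta * sin(theta_L)
  state$time <- state$time + dt
  state
}

#' Steering cost of a control history
#'
#' Trapezoid-rule evaluation of `integral (T(L, t) . u(t))^2 dt`. The cost
#' measures how much the control stretches the tip tangent: it is zero
#' exactly when the control stays perpendicular to the tip tangent, which
#' preserves the arc-length parameterization — the optimal control family
#' zeroes the integrand identically.
#'
#' @param tip_tangents Matrix, one unit tip tangent 2-vector per row.
#' @param controls Matrix, one control 2-vector per row (same row count).
#' @param dt Sampling interval of the rows.
#' @return Scalar cost.
#' @export
cost_functional <- function(tip_tangents, controls, dt) {
  stopifnot(nrow(tip_tangents) == nrow(controls), dt > 0)
  f <- rowSums(tip_tangents * controls)^2
  m <- length(f)
  if (m < 2) return(0)
  dt * (sum(f) - (f[1] + f[m]) / 2)
}

#' One step of the apical-sensing angle dynamics
#'
#' Integrates `d/dt d/ds theta(s, t) = -sin(theta(L, t))`: the time step
#' adds `-sin(theta(L)) * dt` uniformly to the arc derivative of the angle,
#' and the angle field is rebuilt by cumulative integration from the clamped
#' base. Equivalent to [evolve_tangent()] with unit gain, kept as a separate
#' formulation for cross-checking.
#'
#' @param theta_field Numeric vector on the arc grid `s = 0, ds, ..., L`
#'   (base entry fixed).
#' @param ds Arc-grid spacing.
#' @param dt Time step.
#' @return The updated angle field.
#' @export
apical_dynamics_theta <- function(theta_field, ds, dt) {
  n <- length(theta_field)
  if (n < 2) return(theta_field)
  w <- diff(theta_field) / ds                 # d theta / ds per cell
  w <- w - sin(theta_field[n]) * dt
  c(theta_field[1], theta_field[1] + cumsum(w * ds))
}

#' Simulate apical tip steering to alignment
#'
#' Runs [evolve_tangent()] from an initial angle field until the tip angle
#' magnitude drops below `tol` or `max_steps` is reached, recording the tip
#' angle, tip tangent, and emitted control at every step, plus the
#' accumulated steering cost.
#'
#' @param theta0 Initial angle field (vector incl. the base entry), or a
#'   single number for a uniformly inclined organ above a clamped base.
#' @param ds Arc-grid spacing (ignored if `theta0` is a full field of given
#'   length; the grid spans `[0, L]`).
#' @param n_grid Grid size when `theta0` is scalar.
#' @param beta Control gain.
#' @param dt Time step.
#' @param tol Stop once `|theta(L)| < tol`.
#' @param max_steps Step cap.
#' @param n_hat Stimulus direction.
#' @return List with `theta` (final field), `tip_angle` (per-step series),
#'   `tip_tangents`, `controls`, `cost`, `times`, `state`.
#' @export
apical_control_sim <- function(theta0, ds = NULL, n_grid = 21, beta = 1,
                               dt = 0.05, tol = 1e-4, max_steps = 20000,
                               n_hat = c(0, 1)) {
  if (length(theta0) == 1) {
    if (is.null(ds)) ds <- 1 / (n_grid - 1)
    theta0 <- c(0, rep(theta0, n_grid - 1))
  } else if (is.null(ds)) {
    ds <- 1 / (length(theta0) - 1)
  }
  st <- control_state(theta0, ds, n_hat = n_hat, beta = beta)
  tip_angle <- numeric(0); tangents <- NULL; controls <- NULL
  for (m in seq_len(max_steps)) {
    n <- length(st$theta)
    tip_angle[m] <- st$theta[n]
    tg <- control_tangents(st)[n, ]
    u <- control_input(tg, st$n_hat, st$beta)
    tangents <- rbind(tangents, tg)
    controls <- rbind(controls, u)
    if (abs(st$theta[n]) < tol) break
    st <- evolve_tangent(st, dt)
  }
  list(theta = st$theta, tip_angle = tip_angle,
       tip_tangents = tangents, controls = controls,
       cost = cost_functional(tangents, controls, dt),
       times = (seq_along(tip_angle) - 1) * dt, state = st)
}
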