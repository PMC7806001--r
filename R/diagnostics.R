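#' Characteristic length and time scales of tropic dynamics
#'
#' From the planar reduction of the curvature dynamics one reads off:
#' * convergence length `Lc = gamma / lambda` — the steady-state radius of
#'   curvature (its inverse `kappa_max = lambda / gamma` is the maximal
#'   steady-state curvature);
#' * convergence time `Tc = R / (E * gamma)` — time for the organ shape to
#'   reach steady state;
#' * arrival time `Tv = R / (E * Lgz * lambda)` — time for the tip to first
#'   align with the stimulus;
#' * balance number `B = lambda * Lgz / gamma = Lgz / Lc = Tc / Tv` —
#'   dimensionless ratio of tropic to proprioceptive sensitivity. High `B`:
#'   the tip aligns before the shape converges (damped oscillations); low
#'   `B`: the shape converges before alignment.
#'
#' @param lambda_ Tropic sensitivity (> 0).
#' @param gamma Proprioceptive sensitivity (> 0).
#' @param Lgz Growth-zone length (> 0).
#' @param R Organ radius (> 0).
#' @param growth_rate Elongation rate `E` (> 0).
#' @return An object of class `characteristic_scales` with fields `Lc`,
#'   `Tc`, `Tv`, `B`, `kappa_max_pred`.
#' @examples
#' characteristic_scales(0.1, 0.01, 1, 0.1, 0.1)  # B = 10
#' @export
characteristic_scales <- function(lambda_, gamma, Lgz, R, growth_rate) {
  if (any(c(lambda_, gamma, Lgz, R, growth_rate) <= 0))
    stop("all parameters must be > 0", call. = FALSE)
  structure(
    list(Lc = gamma / lambda_,
         Tc = R / (growth_rate * gamma),
         Tv = R / (growth_rate * Lgz * lambda_),
         B = lambda_ * Lgz / gamma,
         kappa_max_pred = lambda_ / gamma),
    class = "characteristic_scales")
}

#' @export
print.characteristic_scales <- function(x, ...) {
  cat(sprintf("<characteristic_scales> B = %g\n", x$B))
  cat(sprintf("  Lc = %g, Tc = %g, Tv = %g, kappa_max = %g\n",
              x$Lc, x$Tc, x$Tv, x$kappa_max_pred))
  invisible(x)
}

#' Independent planar curvature-dynamics integrator (validation oracle)
#'
#' Integrates the planar reduction of the model,
#' `D kappa / Dt = (E / R) (-lambda sin(theta) - gamma kappa)` with
#' `theta(s) = theta_base + integral of kappa ds`, on the same grid and with
#' the same explicit stepping, upwind advection, clamped base and
#' tip-segment rule as the 3D scheme — but as plain scalar arithmetic on the
#' angle field, sharing no geometry code with the 3D simulator. For an
#' initially vertical organ and a horizontal stimulus, `theta_base = pi/2`
#' and the 3D run's `kappa1` field equals `-kappa` of this oracle.
#'
#' @param lambda_ Tropic sensitivity (>= 0).
#' @param gamma Proprioceptive sensitivity (>= 0).
#' @param config A [sim_config()] supplying `R`, `Lgz`, `L0`, `dt`, `ds`,
#'   `growth_rate`.
#' @param n_steps Number of steps to integrate.
#' @param kappa0 Optional initial curvature profile (default straight).
#' @param theta_base Angle between the base tangent and the stimulus.
#' @param advection Include the growth-flow advection term (set `FALSE` for
#'   the pure material-point decay limit).
#' @return List with `kappa`, a list of per-step curvature fields (step 0 to
#'   `n_steps`), and `times`.
#' @export
ace_oracle_2d <- function(lambda_, gamma, config, n_steps,
                          kappa0 = NULL, theta_base = pi / 2,
                          advection = TRUE) {
  ds <- config$ds; dt <- config$dt
  Lgz <- config$Lgz; Edot <- config$growth_rate; R <- config$R
  n <- as.integer(round(config$L0 / ds))
  kap <- if (is.null(kappa0)) numeric(n) else as.numeric(kappa0)
  stopifnot(length(kap) == n)
  hist <- vector("list", n_steps + 1)
  hist[[1]] <- kap
  for (m in seq_len(n_steps)) {
    nn <- length(kap)
    theta <- theta_base + ds * c(0, cumsum(kap)[-nn])
    src <- (Edot / R) * (-lambda_ * sin(theta) - gamma * kap)
    if (advection) {
      vel <- pmax(Lgz - (nn - seq_len(nn)) * ds, 0) * Edot
      src <- src - vel * (kap - c(0, kap[-nn])) / ds
    }
    kap <- kap + dt * src
    kap[1] <- 0
    kap <- c(kap, kap[nn])          # new tip segment copies its predecessor
    hist[[m + 1]] <- kap
  }
  list(kappa = hist, times = (0:n_steps) * dt)
}

#' Accretive-growth comparison integrator
#'
#' Integrates the planar accretive-growth model
#' `d kappa(s, t) / dt = -lambda * exp(-eta (t - s)) * sin(theta(s, t))`,
#' in which material is deposited at the tip (`s = t`) and older material
#' stiffens exponentially at rate `eta`, standing in for an explicit growth
#' zone and proprioception. No material derivative is needed. Provided for
#' qualitative comparison with the growth-based planar dynamics.
#'
#' @param lambda_ Response-strength constant (>= 0).
#' @param eta Stiffening rate; `1 / eta` is the effective growth-zone size.
#' @param grid List with `ds`, `dt`, `n_steps`, `kappa0` (initial curvature
#'   field; its length sets the arc grid), `theta_base` (angle of the base
#'   tangent to the stimulus) and `t0` (initial time, defaulting to the organ
#'   length so that the newest material sits at `s = t`).
#' @return List with `kappa`, a list of per-step curvature fields, and
#'   `times`.
#' @export
bressan_oracle_2d <- function(lambda_, eta, grid) {
  ds <- grid$ds; dt <- grid$dt
  kap <- as.numeric(grid$kappa0)
  n <- length(kap)
  theta_base <- if (is.null(grid$theta_base)) pi / 2 else grid$theta_base
  t0 <- if (is.null(grid$t0)) n * ds else grid$t0
  s <- (seq_len(n) - 1) * ds
  hist <- vector("list", grid$n_steps + 1)
  hist[[1]] <- kap
  for (m in seq_len(grid$n_steps)) {
    t <- t0 + (m - 1) * dt
    theta <- theta_base + ds * c(0, cumsum(kap)[-n])
    kap <- kap + dt * (-lambda_ * exp(-eta * (t - s)) * sin(theta))
    hist[[m + 1]] <- kap
  }
  list(kappa = hist, times = t0 + (0:grid$n_steps) * dt)
}

#' Maximal curvature at steady state
#'
#' Returns the maximum of `|kappa|` over the organ at the last recorded
#' state of a trajectory. At steady state under a constant stimulus this
#' equals the ratio of tropic to proprioceptive sensitivity,
#' `kappa_max = lambda / gamma`. The attached `converged` attribute reports
#' whether the run satisfied the steady-state criterion; a warning is issued
#' if it did not.
#'
#' @param record A `growth_trajectory` from [grow_sim()].
#' @return Scalar `max |kappa|` with attribute `converged`.
#' @export
steady_state_kappa_max <- function(record) {
  stopifnot(inherits(record, "growth_trajectory"))
  val <- record$kappa_max[length(record$kappa_max)]
  if (!isTRUE(record$converged))
    warning("trajectory did not satisfy the steady-state criterion",
            call. = FALSE)
  structure(val, converged = isTRUE(record$converged))
}
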