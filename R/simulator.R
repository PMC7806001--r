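#' Simulation configuration
#'
#' Single source of truth for a run: physical parameters, numerical
#' parameters, and the scenario. Defaults reproduce the reference parameter
#' set: organ radius `R = 0.1`, proprioceptive sensitivity `gamma = 0.01`,
#' tropic sensitivities `lambda0 = 0.1` and `lambda1 = 0.05`, growth zone
#' `Lgz = 1`, initial length `L0 = 1`, time step `dt = 0.1`, segment length
#' `ds = 0.01`, growth rate `E = 0.1`, circumnutation frequency
#' `omega = 0.2 / dt`. All quantities are in dimensionless model units.
#'
#' The grid relation `ds = Lgz * E * dt` (exactly one segment added per step)
#' is a hard constraint: configurations violating it beyond 1e-9 relative are
#' rejected with an error rather than silently adjusted.
#'
#' @param scenario One of `"distant"` (constant stimulus at infinity),
#'   `"point"` (point source), `"line_twine"` (attracting line plus an axial
#'   stimulus, producing twining), `"circumnutation"` (internal oscillator
#'   only), `"superposition"` (distant stimulus plus circumnutation), or
#'   `"custom"` (terms supplied via `custom_spec`).
#' @param n_steps Number of time steps.
#' @param R,gamma,lambda0,lambda1,Lgz,L0,dt,ds,growth_rate,omega Physical and
#'   numerical parameters, see above.
#' @param direction Stimulus direction for the distant/superposition
#'   scenarios (default perpendicular to the initial vertical organ).
#' @param source Source position for the point scenario.
#' @param line_base,line_axis Base point and direction of the line stimulus.
#' @param sensing `"local"` or `"apical"` sensing for tropic terms.
#' @param record_every Record a full state snapshot every this many steps
#'   (tip diagnostics are recorded every step regardless).
#' @param stop_on_steady Stop once the steady-state criterion holds:
#'   `max |kappa(m) - kappa(m-1)| / dt < steady_tol` for `steady_window`
#'   consecutive steps.
#' @param steady_tol,steady_window Steady-state criterion parameters.
#' @param custom_spec Optional [growth_spec()] used when
#'   `scenario = "custom"` (default: no differential growth beyond
#'   proprioception).
#' @param random_seed Reserved; all provided scenarios are deterministic.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scenario = c("distant", "point", "line_twine",
                                    "circumnutation", "superposition",
                                    "custom"),
                       n_steps = 500,
                       R = 0.1, gamma = 0.01, lambda0 = 0.1, lambda1 = 0.05,
                       Lgz = 1.0, L0 = 1.0, dt = 0.1, ds = 0.01,
                       growth_rate = 0.1, omega = 0.2 / dt,
                       direction = c(1, 0, 0),
                       source = c(1.5, 0, 1.5),
                       line_base = c(0.3, 0, 0), line_axis = c(0, 0, 1),
                       sensing = c("local", "apical"),
                       record_every = 1L,
                       stop_on_steady = FALSE, steady_tol = 1e-6,
                       steady_window = 50L,
                       custom_spec = NULL, random_seed = NULL) {
  scenario <- match.arg(scenario)
  sensing <- match.arg(sensing)
  cfg <- structure(
    list(scenario = scenario, n_steps = as.integer(n_steps),
         R = as.numeric(R), gamma = as.numeric(gamma),
         lambda0 = as.numeric(lambda0), lambda1 = as.numeric(lambda1),
         Lgz = as.numeric(Lgz), L0 = as.numeric(L0), dt = as.numeric(dt),
         ds = as.numeric(ds), growth_rate = as.numeric(growth_rate),
         omega = as.numeric(omega), direction = as.numeric(direction),
         source = as.numeric(source), line_base = as.numeric(line_base),
         line_axis = as.numeric(line_axis), sensing = sensing,
         record_every = as.integer(record_every),
         stop_on_steady = isTRUE(stop_on_steady), steady_tol = steady_tol,
         steady_window = as.integer(steady_window),
         custom_spec = custom_spec, random_seed = random_seed),
    class = "sim_config")
  validate_config(cfg)
}

#' @rdname sim_config
#' @param config A `sim_config` to validate.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (!all(c(R, gamma >= 0, Lgz, L0, dt, ds, growth_rate) > 0) ||
        gamma < 0)
      stop("R, Lgz, L0, dt, ds, growth_rate must be > 0 and gamma >= 0",
           call. = FALSE)
    ds_req <- step_size_relation(Lgz, growth_rate, dt)
    if (abs(ds - ds_req) > 1e-9 * ds_req)
      stop(sprintf(paste0(
        "step-size relation ds = Lgz * E * dt violated: ",
        "ds = %g but Lgz * E * dt = %g * %g * %g = %g"),
        ds, Lgz, growth_rate, dt, ds_req), call. = FALSE)
    if (Lgz > L0 + 1e-9 * L0)
      stop("growth zone Lgz must fit in the initial length L0", call. = FALSE)
    if (abs(L0 / ds - round(L0 / ds)) > 1e-6)
      stop("L0 must be an integer multiple of ds", call. = FALSE)
    if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  })
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> scenario = %s, n_steps = %d\n",
              x$scenario, x$n_steps))
  cat(sprintf("  R = %g, gamma = %g, lambda0 = %g, lambda1 = %g\n",
              x$R, x$gamma, x$lambda0, x$lambda1))
  cat(sprintf("  Lgz = %g, L0 = %g, dt = %g, ds = %g, E = %g, omega = %g\n",
              x$Lgz, x$L0, x$dt, x$ds, x$growth_rate, x$omega))
  invisible(x)
}

#' Build the differential-growth specification for a scenario
#'
#' Translates a configuration into the additive differential-growth terms:
#' * `distant`: `Delta = lambda0 * n - gamma * kappa * N` — constant stimulus
#'   at infinity in direction `n`.
#' * `point`: `Delta = lambda0 * (rp - r)/|rp - r| - gamma * kappa * N` —
#'   radial attraction toward the source at `rp`.
#' * `line_twine`: `Delta = lambda0 * z - lambda1 * rho_hat - gamma kappa N`
#'   — attraction toward a line (shortest displacement `rho`) plus an axial
#'   stimulus along the line, yielding twining.
#' * `circumnutation`:
#'   `Delta = lambda0 (cos(omega t) m1 + sin(omega t) m2) - gamma kappa N`.
#' * `superposition`: distant stimulus of strength `lambda0` plus a
#'   circumnutation term of strength `lambda1`.
#'
#' Tropic terms use a linear (Stevens, exponent 1) sensitivity on a
#' unit-magnitude field, so the evaluated response reproduces the scenario
#' formulas exactly: a vector `lambda * n` projected onto the cross-section.
#'
#' @param config A [sim_config()].
#' @return A [growth_spec()].
#' @export
build_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lin <- function(lambda) sensitivity_stevens(a = lambda, b = 1)
  terms <- list()
  circ <- NULL
  psi_fun <- local({
    om <- config$omega
    function(t) om * t
  })
  min_d <- 1e-9 * config$ds
  switch(config$scenario,
    distant = {
      terms <- list(tropic_term(stimulus_constant(config$direction),
                                lin(config$lambda0), sign = 1,
                                sensing = config$sensing))
    },
    point = {
      terms <- list(tropic_term(
        stimulus_point(config$source, min_distance = min_d),
        lin(config$lambda0), sign = 1, sensing = config$sensing))
    },
    line_twine = {
      terms <- list(
        tropic_term(stimulus_constant(config$line_axis),
                    lin(config$lambda0), sign = 1, sensing = config$sensing),
        tropic_term(stimulus_line(config$line_base, config$line_axis),
                    lin(config$lambda1), sign = 1, sensing = config$sensing))
    },
    circumnutation = {
      circ <- list(lambda_c = config$lambda0, psi = psi_fun)
    },
    superposition = {
      terms <- list(tropic_term(stimulus_constant(config$direction),
                                lin(config$lambda0), sign = 1,
                                sensing = config$sensing))
      circ <- list(lambda_c = config$lambda1, psi = psi_fun)
    },
    custom = {
      if (!is.null(config$custom_spec)) return(config$custom_spec)
    },
    stop("unknown scenario: ", config$scenario, call. = FALSE)
  )
  growth_spec(tropic_terms = terms, circumnutation = circ,
              gamma = config$gamma, growth_rate = config$growth_rate)
}

#' Run a full growth simulation
#'
#' Starting from a straight vertical organ of length `L0` (base triad
#' `m1 = x`, `m2 = y`, `T = z`, clamped base), executes `n_steps` of the
#' explicit scheme: evaluate the differential growth vector on the current
#' geometry, advance the curvature components (upwind advection through the
#' growth zone), append the newly grown tip segment, and reconstruct frames
#' and positions. Runs are fully deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return An object of class `growth_trajectory`: recorded times, organ
#'   state snapshots with derived curvature/torsion fields, per-step tip
#'   diagnostics, and the steady-state flag. Access snapshots via
#'   `$states`, per-step tip tangents via `$step_tip_tangent`.
#' @examples
#' cfg <- sim_config("distant", n_steps = 50, record_every = 10)
#' traj <- grow_sim(cfg)
#' summary(traj)
#' @export
grow_sim <- function(config) {
  config <- validate_config(config)
  spec <- build_scenario(config)
  ds <- config$ds; dt <- config$dt
  Lgz <- config$Lgz; Edot <- config$growth_rate
  n0 <- as.integer(round(config$L0 / ds))
  n_steps <- config$n_steps
  nmax <- n0 + n_steps
  base_frame <- diag(3)
  base_pos <- c(0, 0, 0)

  k1 <- numeric(nmax); k2 <- numeric(nmax)
  n <- n0

  rec_times <- c(); rec_states <- list(); rec_kappa <- list()
  rec_phi <- list(); rec_tau <- list(); rec_tip_frame <- list()
  rec_tip_pos <- NULL; rec_tip_normal <- NULL; rec_kmax <- c()
  step_tip_tangent <- matrix(NA_real_, n_steps + 1, 3)
  step_kappa_max <- numeric(n_steps + 1)
  steady_run <- 0L; converged <- FALSE; converged_step <- NA_integer_
  last_step <- n_steps

  light_state <- function() {
    structure(list(kappa1 = k1[seq_len(n)], kappa2 = k2[seq_len(n)],
                   ds = ds, n_segments = n, radius = config$R,
                   growth_zone_length = Lgz, base_frame = base_frame,
                   base_position = base_pos),
              class = "organ_state")
  }

  for (m in 0:n_steps) {
    kk1 <- k1[seq_len(n)]; kk2 <- k2[seq_len(n)]
    fr <- propagate_frames_cpp(kk1, kk2, ds, base_frame, base_pos)
    step_tip_tangent[m + 1, ] <- fr$tangent[n, ]
    step_kappa_max[m + 1] <- sqrt(max(kk1^2 + kk2^2))

    record_now <- (m %% config$record_every == 0) || m == n_steps ||
      (converged && config$stop_on_steady)
    if (record_now) {
      fs <- frenet_from_natural(kk1, kk2, ds)
      rec_times <- c(rec_times, m * dt)
      rec_states[[length(rec_states) + 1L]] <- light_state()
      rec_kappa[[length(rec_kappa) + 1L]] <- fs$kappa
      rec_phi[[length(rec_phi) + 1L]] <- fs$phi
      rec_tau[[length(rec_tau) + 1L]] <- fs$tau
      rec_tip_frame[[length(rec_tip_frame) + 1L]] <- frame_at(fr, n)
      rec_tip_pos <- rbind(rec_tip_pos, fr$positions[n + 1, ])
      tipn <- if (fs$kappa[n] > 0)
        cos(fs$phi[n]) * fr$m1[n, ] + sin(fs$phi[n]) * fr$m2[n, ]
      else c(NA_real_, NA_real_, NA_real_)
      rec_tip_normal <- rbind(rec_tip_normal, tipn)
      rec_kmax <- c(rec_kmax, max(fs$kappa))
    }
    if (m == n_steps || (converged && config$stop_on_steady)) {
      last_step <- m
      break
    }

    # differential growth on current geometry, then curvature update
    st <- light_state()
    delta <- differential_growth_vector(st, fr, spec, t = m * dt)
    v <- pmax(Lgz - (n - seq_len(n)) * ds, 0) * Edot
    k <- step_curvature_core(kk1, kk2, delta, v, dt, Edot, config$R, ds)
    if (!all(is.finite(k[[1]])) || !all(is.finite(k[[2]])))
      stop(sprintf("numerical blow-up at step %d: non-finite curvature", m + 1),
           call. = FALSE)

    dk <- max(abs(k[[1]] - kk1), abs(k[[2]] - kk2)) / dt
    if (dk < config$steady_tol) steady_run <- steady_run + 1L
    else steady_run <- 0L
    if (!converged && steady_run >= config$steady_window) {
      converged <- TRUE
      converged_step <- m + 1L
    }

    # tip segment grown this step inherits its predecessor's curvature
    k1[seq_len(n)] <- k[[1]]; k2[seq_len(n)] <- k[[2]]
    k1[n + 1L] <- k[[1]][n]; k2[n + 1L] <- k[[2]][n]
    n <- n + 1L
  }

  structure(
    list(config = config, spec = spec,
         times = rec_times, states = rec_states,
         kappa = rec_kappa, phi = rec_phi, tau = rec_tau,
         tip_position = rec_tip_pos, tip_frame = rec_tip_frame,
         tip_normal = rec_tip_normal, kappa_max = rec_kmax,
         step_times = (0:last_step) * dt,
         step_tip_tangent = step_tip_tangent[seq_len(last_step + 1), ,
                                             drop = FALSE],
         step_kappa_max = step_kappa_max[seq_len(last_step + 1)],
         n_steps_run = last_step,
         converged = converged, converged_step = converged_step),
    class = "growth_trajectory")
}

#' @export
print.growth_trajectory <- function(x, ...) {
  st <- x$states[[length(x$states)]]
  cat(sprintf("<growth_trajectory> scenario = %s, %d steps run\n",
              x$config$scenario, x$n_steps_run))
  cat(sprintf("  final: N = %d segments, L = %g, max |kappa| = %g\n",
              st$n_segments, st$n_segments * st$ds,
              x$kappa_max[length(x$kappa_max)]))
  cat(sprintf("  tip at (%.4g, %.4g, %.4g); steady state: %s\n",
              x$tip_position[nrow(x$tip_position), 1],
              x$tip_position[nrow(x$tip_position), 2],
              x$tip_position[nrow(x$tip_position), 3],
              if (x$converged) sprintf("reached at step %d", x$converged_step)
              else "not reached"))
  invisible(x)
}

#' @export
summary.growth_trajectory <- function(object, ...) {
  cfg <- object$config
  scales <- if (cfg$lambda0 > 0 && cfg$gamma > 0)
    characteristic_scales(cfg$lambda0, cfg$gamma, cfg$Lgz, cfg$R,
                          cfg$growth_rate)
  else NULL
  out <- list(trajectory = object, scales = scales)
  class(out) <- "summary.growth_trajectory"
  out
}

#' @export
print.summary.growth_trajectory <- function(x, ...) {
  print(x$trajectory)
  if (!is.null(x$scales)) {
    s <- x$scales
    cat(sprintf(paste0("  scales: B = %g, Lc = %g, Tc = %g, Tv = %g, ",
                       "predicted kappa_max = %g\n"),
                s$B, s$Lc, s$Tc, s$Tv, s$kappa_max_pred))
  }
  invisible(x)
}

#' @export
plot.growth_trajectory <- function(x, step = length(x$states), ...) {
  st <- x$states[[step]]
  fr <- propagate_frames(st)
  nhist <- x$tip_normal[seq_len(step), , drop = FALSE]
  plot_snapshot(st, fr, n_history = nhist, ...)
  invisible(x)
}
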