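#' Differential-growth specification
#'
#' Bundles the mechanisms that bend a growing organ, assumed additive:
#' tropic responses to external stimuli, an internal circumnutation
#' oscillator, and proprioceptive posture control (`-gamma * kappa * N`,
#' the active tendency of the organ to straighten in proportion to its own
#' curvature).
#'
#' @param tropic_terms List of tropic terms, each built by [tropic_term()].
#' @param circumnutation `NULL`, or a list with `lambda_c` (bending
#'   intensity) and `psi`, a function of time giving the cross-sectional
#'   direction of the oscillator (e.g. `function(t) omega * t`).
#' @param gamma Proprioceptive sensitivity (units length; `gamma * kappa` is
#'   dimensionless). Must be >= 0.
#' @param growth_rate Uniform relative elongation rate `E` in the growth
#'   zone (1/time). Must be >= 0.
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(tropic_terms = list(), circumnutation = NULL,
                        gamma = 0.01, growth_rate = 0.1) {
  stopifnot(gamma >= 0, growth_rate >= 0)
  structure(list(tropic_terms = tropic_terms, circumnutation = circumnutation,
                 gamma = gamma, growth_rate = growth_rate),
            class = "growth_spec")
}

#' @rdname growth_spec
#' @param field A [stimulus_field].
#' @param sens A [sensitivity_function].
#' @param sign `+1` for attraction (growth toward the stimulus), `-1` for
#'   repulsion. The response-vector convention carries a minus sign, so the
#'   attract/repel choice is owned here by the term, keeping the scenario
#'   formulas reproduced verbatim.
#' @param sensing `"local"` (distributed sensors respond to the stimulus at
#'   their own position) or `"apical"` (the tip's response is broadcast,
#'   component-wise in the natural frame, to the whole organ).
#' @export
tropic_term <- function(field, sens, sign = 1, sensing = c("local", "apical")) {
  sensing <- match.arg(sensing)
  stopifnot(inherits(field, "stimulus_field"), sign %in% c(-1, 1))
  list(field = field, sens = sens, sign = sign, sensing = sensing)
}

#' Differential growth vector in natural-frame components
#'
#' Assembles, per segment, the cross-sectional components of the differential
#' growth vector: the sum of all tropic response vectors (local or apically
#' broadcast), the circumnutation term
#' `lambda_c * (cos(psi) m1 + sin(psi) m2)`, and the proprioceptive term
#' `-gamma * kappa * N` (evaluated as `-gamma * (kappa1, kappa2)`, which is
#' well-defined even where `kappa = 0`). Only these two components enter the
#' curvature dynamics.
#'
#' @param state An [organ_state()].
#' @param frames Result of [propagate_frames()] for `state`.
#' @param spec A [growth_spec()].
#' @param t Current time.
#' @return `N` x 2 matrix: columns `(Delta . m1, Delta . m2)` per segment.
#' @export
differential_growth_vector <- function(state, frames, spec, t = 0) {
  n <- state$n_segments
  delta <- matrix(0, n, 2)
  m1 <- frames$m1; m2 <- frames$m2; tg <- frames$tangent
  pos <- frames$positions[seq_len(n), , drop = FALSE]

  for (term in spec$tropic_terms) {
    if (term$sensing == "local") {
      ev <- eval_stimulus(term$field, pos)
      sig <- ev$direction * ev$magnitude
      dot_t <- rowSums(sig * tg)
      perp <- sig - tg * dot_t
      I_perp <- sqrt(rowSums(perp^2))
      lam <- rep(0, n)
      ok <- is.finite(I_perp) & I_perp > 0
      lam[ok] <- term$sens(I_perp[ok])
      scale <- ifelse(ok, term$sign * lam / pmax(I_perp, .Machine$double.xmin), 0)
      delta[, 1] <- delta[, 1] + scale * rowSums(perp * m1)
      delta[, 2] <- delta[, 2] + scale * rowSums(perp * m2)
    } else {  # apical: sense at the tip, broadcast components everywhere
      tip_pos <- frames$positions[n + 1, ]
      tip_tan <- tg[n, ]
      ev <- eval_stimulus(term$field, matrix(tip_pos, 1, 3))
      sig <- ev$magnitude[1] * ev$direction[1, ]
      perp <- perpendicular_component(sig, tip_tan)
      I_perp <- sqrt(sum(perp^2))
      if (I_perp > 0) {
        u <- perp / I_perp
        lam <- term$sens(I_perp)
        delta[, 1] <- delta[, 1] + term$sign * lam * sum(u * m1[n, ])
        delta[, 2] <- delta[, 2] + term$sign * lam * sum(u * m2[n, ])
      }
    }
  }

  if (!is.null(spec$circumnutation)) {
    psi <- spec$circumnutation$psi(t)
    delta[, 1] <- delta[, 1] + spec$circumnutation$lambda_c * cos(psi)
    delta[, 2] <- delta[, 2] + spec$circumnutation$lambda_c * sin(psi)
  }

  delta[, 1] <- delta[, 1] - spec$gamma * state$kappa1
  delta[, 2] <- delta[, 2] - spec$gamma * state$kappa2
  delta
}

#' Growth-induced velocity profile along the organ
#'
#' The material velocity at segment `n` is the accumulated elongation of all
#' growing material below it: with a uniform growth rate over a sub-apical
#' growth zone of length `Lgz`,
#' `v(n) = (Lgz - (N - n) * ds) * E` where that is positive, and 0 in the
#' mature (non-growing) region. The tip moves at `Lgz * E`.
#'
#' @param state An [organ_state()].
#' @param growth_rate Elongation rate `E` (1/time).
#' @return Numeric vector of per-segment velocities, non-decreasing in `n`.
#' @export
growth_velocity <- function(state, growth_rate) {
  n <- state$n_segments
  stopifnot(state$growth_zone_length <= n * state$ds + 1e-9)
  pmax(state$growth_zone_length - (n - seq_len(n)) * state$ds, 0) * growth_rate
}

#' Advance curvature components one explicit time step
#'
#' The discrete material derivative of each curvature component combines the
#' differential-growth source `(E / R) * Delta_i` with upwind (backward
#' difference) advection by the growth velocity:
#' `kappa_i(n, m+1) = kappa_i(n, m) + dt * ((E/R) Delta_i(n)
#'   - v(n) (kappa_i(n) - kappa_i(n-1)) / ds)`.
#' The base row stays clamped at zero. Since `v >= 0` (material flows toward
#' the tip), the backward difference is the stable upwind choice.
#'
#' @param state An [organ_state()].
#' @param delta `N` x 2 matrix from [differential_growth_vector()].
#' @param v Per-segment velocities from [growth_velocity()].
#' @param dt Time step (> 0).
#' @param growth_rate Elongation rate `E`.
#' @return The updated [organ_state()].
#' @export
step_curvature <- function(state, delta, v, dt, growth_rate) {
  stopifnot(dt > 0, nrow(delta) == state$n_segments,
            length(v) == state$n_segments)
  k <- step_curvature_core(state$kappa1, state$kappa2, delta, v, dt,
                           growth_rate, state$radius, state$ds)
  st <- state
  st$kappa1 <- k[[1]]
  st$kappa2 <- k[[2]]
  st
}

# raw-vector kernel shared with the simulator loop
step_curvature_core <- function(kappa1, kappa2, delta, v, dt,
                                growth_rate, radius, ds) {
  n <- length(kappa1)
  src <- growth_rate / radius
  adv1 <- v * (kappa1 - c(0, kappa1[-n])) / ds
  adv2 <- v * (kappa2 - c(0, kappa2[-n])) / ds
  k1 <- kappa1 + dt * (src * delta[, 1] - adv1)
  k2 <- kappa2 + dt * (src * delta[, 2] - adv2)
  k1[1] <- 0
  k2[1] <- 0
  list(k1, k2)
}

#' Append the new tip segment grown during one step
#'
#' One segment of length `ds` is added at the apex per time step, so the
#' segment count obeys `N(m) = N(0) + m`. The incoming segment inherits the
#' curvature of its predecessor (equivalent to initializing it curvature-free
#' one step early with tip velocity and zero differential growth).
#'
#' @param state An [organ_state()].
#' @return The [organ_state()] with one more segment.
#' @export
add_tip_segment <- function(state) {
  n <- state$n_segments
  st <- state
  st$kappa1 <- c(state$kappa1, state$kappa1[n])
  st$kappa2 <- c(state$kappa2, state$kappa2[n])
  st$n_segments <- n + 1L
  st
}

#' Spatial step implied by the temporal step
#'
#' One segment is added per time step while the tip advances at `Lgz * E`,
#' which fixes the grid relation `ds = Lgz * E * dt`. Configurations violating
#' it are rejected at configuration time.
#'
#' @param Lgz Growth-zone length.
#' @param growth_rate Elongation rate `E`.
#' @param dt Time step.
#' @return The segment length `ds`.
#' @export
step_size_relation <- function(Lgz, growth_rate, dt) {
  stopifnot(Lgz > 0, growth_rate > 0, dt > 0)
  Lgz * growth_rate * dt
}
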