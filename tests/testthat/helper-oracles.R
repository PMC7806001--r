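# Independent oracles used across tests. These deliberately share no code
# with the package internals beyond base arithmetic.

# Brute-force matrix exponential by series summation.
expm_series <- function(A, n_terms = 30) {
  out <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(n_terms)) {
    term <- term %*% A / k
    out <- out + term
  }
  out
}

# Reference first-order upwind advection step for a scalar field.
upwind_advect <- function(field, v, ds, dt) {
  lag <- c(0, field[-length(field)])
  field - dt * v * (field - lag) / ds
}

# Unwrap a cyclic angle series.
unwrap_angles <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(a[1], d))
}

max_ortho_dev <- function(frames) {
  n <- nrow(frames$m1)
  max(vapply(seq_len(n), function(i) {
    D <- rbind(frames$m1[i, ], frames$m2[i, ], frames$tangent[i, ])
    max(abs(D %*% t(D) - diag(3)))
  }, 0))
}

straight_state <- function(n = 100, ds = 0.01,
                           growth_zone_length = n * ds, ...) {
  organ_state(kappa1 = rep(0, n), kappa2 = rep(0, n), ds = ds,
              growth_zone_length = growth_zone_length, ...)
}
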