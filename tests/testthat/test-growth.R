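test_that("proprioception-only differential growth is -gamma * (kappa1, kappa2)", {
  st <- organ_state(kappa1 = c(0, 0.2, 0.1), kappa2 = c(0, 0, -0.3),
                    ds = 0.01, growth_zone_length = 0.03)
  fr <- propagate_frames(st)
  spec <- growth_spec(gamma = 0.01, growth_rate = 0.1)
  d <- differential_growth_vector(st, fr, spec)
  expect_equal(d[2, ], c(-0.002, 0))
  expect_equal(d, cbind(-0.01 * st$kappa1, -0.01 * st$kappa2))
})

test_that("circumnutation term points along the oscillator phase", {
  st <- straight_state(n = 20)
  fr <- propagate_frames(st)
  spec <- growth_spec(circumnutation = list(lambda_c = 0.1,
                                            psi = function(t) 2 * t),
                      gamma = 0, growth_rate = 0.1)
  d0 <- differential_growth_vector(st, fr, spec, t = 0)
  expect_equal(d0, matrix(rep(c(0.1, 0), each = 20), 20, 2))
  dq <- differential_growth_vector(st, fr, spec, t = pi / 4)  # psi = pi/2
  expect_equal(dq, matrix(rep(c(0, 0.1), each = 20), 20, 2),
               tolerance = 1e-12)
})

test_that("line-plus-axial scenario matches direct formula on a hand-built state", {
  lambda0 <- 0.1; lambda1 <- 0.05; gamma <- 0.01
  st <- organ_state(kappa1 = c(0, 0.4, -0.2), kappa2 = c(0, 0.1, 0.3),
                    ds = 0.1, growth_zone_length = 0.3)
  fr <- propagate_frames(st)
  cfg <- sim_config("line_twine", n_steps = 1, lambda0 = lambda0,
                    lambda1 = lambda1, gamma = gamma,
                    line_base = c(0.3, 0.1, 0), line_axis = c(0, 0, 1))
  spec <- build_scenario(cfg)
  d <- differential_growth_vector(st, fr, spec)
  # independent evaluation: Delta = lambda0*z - lambda1*rho_hat - gamma*kappa
  for (i in 1:3) {
    m1 <- fr$m1[i, ]; m2 <- fr$m2[i, ]
    pos <- fr$positions[i, ]
    rel <- pos - c(0.3, 0.1, 0)
    rho <- rel - c(0, 0, 1) * sum(rel * c(0, 0, 1))
    rho_hat <- rho / sqrt(sum(rho^2))
    vec <- lambda0 * c(0, 0, 1) - lambda1 * rho_hat
    expect_equal(d[i, 1], sum(vec * m1) - gamma * st$kappa1[i],
                 tolerance = 1e-12)
    expect_equal(d[i, 2], sum(vec * m2) - gamma * st$kappa2[i],
                 tolerance = 1e-12)
  }
})

test_that("growth velocity is the integrated elongation profile", {
  n <- 200; ds <- 0.01
  st <- straight_state(n = n, ds = ds, growth_zone_length = 1)
  v <- growth_velocity(st, growth_rate = 0.1)
  expect_equal(v[n], 1.0 * 0.1)           # tip moves at Lgz * E
  expect_equal(v[seq_len(n - 100)], rep(0, n - 100))  # mature zone frozen
  expect_equal(v[n - 50], 1.0 * 0.1 / 2)  # midpoint of the growth zone
  expect_true(all(diff(v) >= 0))
})

test_that("curvature step: fixed point, hand-evaluated source, advection oracle", {
  n <- 100; ds <- 0.01; dt <- 0.1; Edot <- 0.1
  st <- straight_state(n = n, ds = ds)
  # zero forcing leaves the state unchanged
  st2 <- step_curvature(st, matrix(0, n, 2), rep(0, n), dt, Edot)
  expect_identical(st2$kappa1, st$kappa1)
  # pure source term: kappa1 = dt * (E/R) * delta = 0.1 * 1 * 0.1 = 0.01
  delta <- cbind(rep(0.1, n), rep(0, n))
  st3 <- step_curvature(st, delta, rep(0, n), dt, Edot)
  expect_equal(st3$kappa1[-1], rep(0.01, n - 1))
  expect_equal(st3$kappa1[1], 0)  # clamped base
  expect_equal(st3$kappa2, rep(0, n))
  # pure advection of a linear profile matches the reference upwind step
  prof <- pmax(seq_len(n) - (n - 50), 0) * 0.002
  prof[1] <- 0
  stp <- organ_state(kappa1 = prof, kappa2 = rep(0, n), ds = ds)
  v <- growth_velocity(stp, Edot)
  st4 <- step_curvature(stp, matrix(0, n, 2), v, dt, Edot)
  ref <- upwind_advect(prof, v, ds, dt)
  ref[1] <- 0
  expect_equal(st4$kappa1, ref, tolerance = 1e-14)
})

test_that("tip segment addition copies the predecessor's curvature", {
  st <- straight_state(n = 10)
  expect_equal(add_tip_segment(st)$kappa1, rep(0, 11))
  st <- organ_state(kappa1 = c(0, 0.5), kappa2 = c(0, -0.2), ds = 0.01,
                    growth_zone_length = 0.02)
  st2 <- add_tip_segment(st)
  expect_equal(st2$n_segments, 3L)
  expect_equal(st2$kappa1[3], 0.5)
  expect_equal(st2$kappa2[3], -0.2)
  # repeated addition: N(m) = N(0) + m
  for (m in 1:5) st2 <- add_tip_segment(st2)
  expect_equal(st2$n_segments, 3L + 5L)
})

test_that("step-size relation ds = Lgz * E * dt", {
  expect_equal(step_size_relation(1.0, 0.1, 0.1), 0.01)
  expect_identical(step_size_relation(1, 1, 1), 1)
  expect_equal(step_size_relation(1, 0.2, 0.1),
               2 * step_size_relation(1, 0.1, 0.1))
})

test_that("proprioception-only dynamics never increase the maximal curvature", {
  n <- 100; ds <- 0.01; dt <- 0.1; Edot <- 0.1
  set.seed(13)
  for (rep_i in 1:3) {
    x <- seq(0, 1, length.out = n)
    a <- stats::runif(2, -1, 1)
    st <- organ_state(kappa1 = a[1] * sin(pi * x)^2 * c(0, rep(1, n - 1)),
                      kappa2 = a[2] * sin(pi * x)^2, ds = ds)
    spec <- growth_spec(gamma = 0.05, growth_rate = Edot)
    kmax_prev <- Inf
    for (m in 1:50) {
      fr <- propagate_frames(st)
      d <- differential_growth_vector(st, fr, spec)
      v <- growth_velocity(st, Edot)
      st <- add_tip_segment(step_curvature(st, d, v, dt, Edot))
      kmax <- max(sqrt(st$kappa1^2 + st$kappa2^2))
      expect_lte(kmax, kmax_prev + 1e-12)
      kmax_prev <- kmax
    }
  }
})
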