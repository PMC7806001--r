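rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

test_that("perpendicular projection obeys the sine law and is idempotent", {
  tg <- c(0, 0, 1)
  expect_equal(perpendicular_component(c(2, 0, 0), tg), c(2, 0, 0))
  expect_equal(perpendicular_component(c(0, 0, 3), tg), c(0, 0, 0))
  set.seed(21)
  for (i in 1:25) {
    tg <- rand_unit()
    sig <- stats::rnorm(3, sd = 2)
    p <- perpendicular_component(sig, tg)
    expect_lt(abs(sum(p * tg)), 1e-12)
    ct <- sum(sig * tg) / sqrt(sum(sig^2))
    expect_equal(sqrt(sum(p^2)), sqrt(sum(sig^2)) * sqrt(1 - ct^2),
                 tolerance = 1e-10)
    expect_equal(perpendicular_component(p, tg), p, tolerance = 1e-12)
  }
})

test_that("response vector follows the sign convention and special cases", {
  field <- stimulus_constant(c(1, 0, 0), magnitude = 2)
  sens <- sensitivity_constant(0.1)
  # tangent perpendicular to the stimulus: magnitude lambda0, direction -n
  rv <- response_vector(field, sens, c(0, 0, 0), c(0, 0, 1))
  expect_equal(rv, c(-0.1, 0, 0))
  # tangent parallel to the stimulus: no directional information
  rv <- response_vector(field, sens, c(0, 0, 0), c(1, 0, 0))
  expect_equal(rv, c(0, 0, 0))
  # linear Stevens law returns the perpendicular intensity itself
  sens <- sensitivity_stevens(1, 1)
  tg <- c(0, sin(pi / 3), cos(pi / 3))
  rv <- response_vector(field, sens, c(0, 0, 0), tg)
  expect_equal(sqrt(sum(rv^2)), 2 * sqrt(1 - sum(tg * c(1, 0, 0))^2),
               tolerance = 1e-12)
})

test_that("response magnitude is bounded by the sensitivity at the source intensity", {
  set.seed(31)
  field <- stimulus_constant(c(0, 1, 0), magnitude = 3)
  for (law in list(sensitivity_constant(0.2), sensitivity_stevens(0.5, 1),
                   sensitivity_stevens(0.1, 2))) {
    for (i in 1:10) {
      rv <- response_vector(field, law, stats::rnorm(3), rand_unit())
      expect_lte(sqrt(sum(rv^2)), law(3) + 1e-12)
    }
  }
})

test_that("sensitivity laws evaluate their formulas", {
  expect_equal(sensitivity_constant(0.7)(c(1, 10, 100)), rep(0.7, 3))
  wf <- sensitivity_weber_fechner(a = 1, b = 2, I0 = 10)
  expect_equal(wf(10), 1)
  expect_equal(wf(10 * exp(1)), 3)
  st <- sensitivity_stevens(a = 2, b = 0.5)
  expect_equal(st(9), 6)
})

test_that("line displacement is the orthogonal offset from the line", {
  expect_equal(line_displacement(c(2, 0, 5), c(0, 0, 0), c(0, 0, 1)),
               c(2, 0, 0))
  expect_equal(line_displacement(c(0, 0, 7), c(0, 0, 0), c(0, 0, 1)),
               c(0, 0, 0))
  set.seed(5)
  for (i in 1:15) {
    d <- rand_unit()
    rho <- line_displacement(stats::rnorm(3, sd = 3), stats::rnorm(3), d)
    expect_lt(abs(sum(rho * d)), 1e-10)
  }
})

test_that("point field responses are mirror-symmetric about the source", {
  src <- c(1, 2, 3)
  field <- stimulus_point(src)
  sens <- sensitivity_constant(0.3)
  off <- c(0.5, -0.2, 0.4)
  tg <- c(0, 0, 1)
  r1 <- response_vector(field, sens, src + off, tg)
  r2 <- response_vector(field, sens, src - off, tg)
  expect_equal(r1, -r2, tolerance = 1e-12)
})

test_that("querying a point source at its own location is a degenerate error", {
  field <- stimulus_point(c(0, 0, 1), min_distance = 1e-9)
  expect_error(response_vector(field, sensitivity_constant(1),
                               c(0, 0, 1), c(1, 0, 0)), "degenerate")
})

test_that("apical broadcast transports cross-sectional components", {
  F1 <- diag(3)  # rows m1, m2, T
  resp <- c(0.3, -0.2, 0.9)
  # identity transport strips the tangential part
  expect_equal(apical_broadcast(resp, F1, F1), c(0.3, -0.2, 0))
  # purely tangential response broadcasts to zero
  expect_equal(apical_broadcast(c(0, 0, 2), F1, F1), c(0, 0, 0))
  # rotated local frame: same components along the local cross-section
  th <- 0.8
  F2 <- rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  out <- apical_broadcast(resp, F1, F2)
  expect_equal(sum(out * F2[1, ]), 0.3, tolerance = 1e-12)
  expect_equal(sum(out * F2[2, ]), -0.2, tolerance = 1e-12)
})

test_that("apical and local sensing coincide on a straight organ", {
  st <- straight_state(n = 60)
  fr <- propagate_frames(st)
  field <- stimulus_constant(c(1, 0, 0))
  sens <- sensitivity_stevens(0.1, 1)
  d_loc <- differential_growth_vector(
    st, fr, growth_spec(list(tropic_term(field, sens, 1, "local")),
                        gamma = 0, growth_rate = 0.1))
  d_api <- differential_growth_vector(
    st, fr, growth_spec(list(tropic_term(field, sens, 1, "apical")),
                        gamma = 0, growth_rate = 0.1))
  expect_equal(d_loc, d_api, tolerance = 1e-14)
})
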