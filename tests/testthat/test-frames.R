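test_that("Darboux matrix has the stated entries and is antisymmetric", {
  expect_equal(darboux_matrix(0, 0), matrix(0, 3, 3))
  U <- darboux_matrix(1, 0)
  expect_equal(U[1, 3], -1)
  expect_equal(U[3, 1], 1)
  expect_equal(sum(abs(U)) , 2)  # all other entries zero
  for (ab in list(c(0.3, -1.2), c(5, 4), c(-0.01, 0))) {
    U <- darboux_matrix(ab[1], ab[2])
    expect_equal(U + t(U), matrix(0, 3, 3))
  }
})

test_that("segment rotation is exp(U ds): identity at zero, SO(3), matches series", {
  expect_equal(segment_rotation(0, 0, 0.01), diag(3))
  set.seed(11)
  for (i in 1:20) {
    k1 <- stats::runif(1, -5, 5); k2 <- stats::runif(1, -5, 5)
    ds <- stats::runif(1, 0.001, 0.2)  # kappa * ds <= 1 regime
    R <- segment_rotation(k1, k2, ds)
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    ref <- expm_series(darboux_matrix(k1, k2) * ds)
    expect_lt(max(abs(R - ref)), 1e-10)
  }
})

test_that("rotation acts about the stated axis by angle kappa*ds", {
  k1 <- 0.8; k2 <- -0.3; ds <- 0.05
  k <- sqrt(k1^2 + k2^2)
  R <- segment_rotation(k1, k2, ds)
  # axis in frame components (m1, m2, T): (k2/k, -k1/k, 0) is fixed
  axis <- c(k2 / k, -k1 / k, 0)
  expect_equal(as.vector(axis %*% R), axis, tolerance = 1e-12)
  # trace gives the rotation angle
  expect_equal((sum(diag(R)) - 1) / 2, cos(k * ds), tolerance = 1e-12)
})

test_that("straight organ reconstructs to a straight vertical line", {
  st <- straight_state(n = 50)
  fr <- propagate_frames(st)
  expect_equal(fr$positions[51, ], c(0, 0, 0.5))
  expect_true(all(abs(fr$tangent - matrix(c(0, 0, 1), 50, 3, byrow = TRUE))
                  == 0))
  expect_lt(max_ortho_dev(fr), 1e-9)
})

test_that("constant-curvature organ matches circular-arc geometry", {
  kap <- 2; n <- 200; ds <- 0.01
  st <- organ_state(kappa1 = c(0, rep(kap, n - 1)), kappa2 = rep(0, n),
                    ds = ds, growth_zone_length = 1)
  fr <- propagate_frames(st)
  # chord length of an arc of radius 1/kappa subtending kappa*(n-1)*ds,
  # up to O(ds) discretization (base segment is straight)
  ang <- kap * (n - 1) * ds
  chord <- 2 / kap * sin(ang / 2)
  dist <- sqrt(sum((fr$positions[n + 1, ] - fr$positions[2, ])^2))
  expect_equal(dist, chord, tolerance = ds * kap)
  # planar: stays in x-z
  expect_true(all(fr$positions[, 2] == 0))
})

test_that("polyline tangents and length agree with frames exactly", {
  set.seed(4)
  st <- organ_state(kappa1 = c(0, stats::rnorm(99, 0, 2)),
                    kappa2 = c(0, stats::rnorm(99, 0, 2)), ds = 0.01)
  fr <- propagate_frames(st)
  diffs <- diff(fr$positions) / st$ds
  expect_equal(diffs, fr$tangent, tolerance = 1e-12)
  len <- sum(sqrt(rowSums(diff(fr$positions)^2)))
  expect_equal(len, st$n_segments * st$ds, tolerance = 1e-12)
  expect_lt(max_ortho_dev(fr), 1e-9)
})

test_that("Frenet descriptors from natural components", {
  fs <- frenet_from_natural(3, 4, 0.01)
  expect_equal(fs$kappa, 5)
  # planar curve: phi and tau vanish where defined
  fs <- frenet_from_natural(c(0, 1, 2, 1), rep(0, 4), 0.1)
  expect_equal(fs$phi[-1], rep(0, 3))
  expect_true(is.na(fs$phi[1]))  # kappa = 0: normal undefined
  expect_equal(fs$tau[3:4], c(0, 0))
  # helical construction: phi = c*s so tau recovers c exactly on the grid
  ds <- 0.01; cc <- 3
  s <- (0:499) * ds
  fs <- frenet_from_natural(cos(cc * s), sin(cc * s), ds)
  expect_equal(fs$kappa, rep(1, 500), tolerance = 1e-12)
  expect_equal(fs$tau[-1], rep(cc, 499), tolerance = 1e-9)
})

test_that("phi unwrapping avoids spurious 2*pi jumps in tau", {
  ds <- 0.01; cc <- 5
  s <- (0:999) * ds  # phi spans > 2*pi
  fs <- frenet_from_natural(cos(cc * s), sin(cc * s), ds)
  expect_lt(max(abs(fs$tau[-1] - cc)), 1e-8)
  expect_gt(max(fs$phi, na.rm = TRUE), 2 * pi)  # unwrapped beyond one turn
})

test_that("organ_state validates its invariants", {
  expect_error(organ_state(c(0.1, 0), c(0, 0), 0.01), "clamped")
  expect_error(organ_state(rep(0, 10), rep(0, 10), 0.01,
                           growth_zone_length = 1), "exceeds")
  badF <- diag(3); badF[1, 1] <- 2
  expect_error(organ_state(rep(0, 100), rep(0, 100), 0.01,
                           base_frame = badF), "orthonormal")
})

test_that("organ state round-trips through text serialization bit-exactly", {
  set.seed(7)
  st <- organ_state(kappa1 = c(0, stats::rnorm(49) / 3),
                    kappa2 = c(0, stats::rnorm(49) / 3),
                    ds = 0.01, radius = 0.1, growth_zone_length = 0.25)
  f <- tempfile(fileext = ".csv")
  write_organ_state(st, f)
  st2 <- read_organ_state(f)
  expect_identical(st2$kappa1, st$kappa1)
  expect_identical(st2$kappa2, st$kappa2)
  expect_identical(st2$ds, st$ds)
  expect_identical(st2$base_frame, st$base_frame)
  expect_identical(st2$growth_zone_length, st$growth_zone_length)
  unlink(f)
})
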