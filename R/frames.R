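#' Discretized organ state in the natural frame
#'
#' Constructs the state of a rod-like organ discretized into `N` segments of
#' arc-length `ds`. The organ centerline is described in a natural (Bishop)
#' frame `(m1, m2, T)`: `kappa1` and `kappa2` are the curvature components of
#' the cross-section plane along `m1` and `m2`, well-defined even where the
#' total curvature vanishes (unlike the Frenet-Serret normal). The base is
#' clamped, so the first segment always carries zero curvature.
#'
#' @param kappa1,kappa2 Numeric vectors of curvature components per segment
#'   (units 1/length), equal length, first entry zero (clamped base).
#' @param ds Segment arc-length (> 0).
#' @param radius Organ radius `R`.
#' @param growth_zone_length Length `Lgz` of the sub-apical growth zone; must
#'   not exceed the total length `N * ds`.
#' @param base_frame 3x3 orthonormal matrix with determinant +1 whose rows are
#'   the base triad `(m1, m2, T)`. Default: `m1 = x`, `m2 = y`, `T = z`
#'   (straight vertical organ).
#' @param base_position Numeric 3-vector, centerline origin.
#' @return An object of class `organ_state`.
#' @examples
#' st <- organ_state(kappa1 = rep(0, 100), kappa2 = rep(0, 100), ds = 0.01)
#' st
#' @export
organ_state <- function(kappa1, kappa2, ds,
                        radius = 0.1, growth_zone_length = 1.0,
                        base_frame = diag(3), base_position = c(0, 0, 0)) {
  kappa1 <- as.numeric(kappa1)
  kappa2 <- as.numeric(kappa2)
  n <- length(kappa1)
  stopifnot(length(kappa2) == n, n >= 1, is.finite(ds), ds > 0)
  if (!all(is.finite(kappa1)) || !all(is.finite(kappa2)))
    stop("non-finite curvature components", call. = FALSE)
  if (abs(kappa1[1]) > 0 || abs(kappa2[1]) > 0)
    stop("clamped base requires kappa1[1] = kappa2[1] = 0", call. = FALSE)
  L <- n * ds
  if (growth_zone_length > L + 1e-9 * L)
    stop("growth zone length exceeds total organ length", call. = FALSE)
  base_frame <- matrix(as.numeric(base_frame), 3, 3)
  if (max(abs(base_frame %*% t(base_frame) - diag(3))) > 1e-10 ||
      abs(det(base_frame) - 1) > 1e-10)
    stop("base_frame must be orthonormal with determinant +1", call. = FALSE)
  structure(
    list(kappa1 = kappa1, kappa2 = kappa2, ds = ds, n_segments = n,
         radius = radius, growth_zone_length = growth_zone_length,
         base_frame = base_frame, base_position = as.numeric(base_position)),
    class = "organ_state")
}

#' @export
print.organ_state <- function(x, ...) {
  kap <- sqrt(x$kappa1^2 + x$kappa2^2)
  cat(sprintf("<organ_state> N = %d segments, ds = %g, L = %g\n",
              x$n_segments, x$ds, x$n_segments * x$ds))
  cat(sprintf("  R = %g, Lgz = %g, max |kappa| = %g\n",
              x$radius, x$growth_zone_length, max(kap)))
  invisible(x)
}

#' Skew-symmetric Darboux matrix
#'
#' The matrix `U` generating the rotation of the natural frame along the
#' arc-length: `dD/ds = U D`, with the frame triad stored as rows
#' `(m1, m2, T)`.
#'
#' @param kappa1,kappa2 Scalar curvature components.
#' @return A 3x3 antisymmetric matrix.
#' @export
darboux_matrix <- function(kappa1, kappa2) {
  stopifnot(is.finite(kappa1), is.finite(kappa2))
  matrix(c(0, 0, -kappa1,
           0, 0, -kappa2,
           kappa1, kappa2, 0), nrow = 3, byrow = TRUE)
}

#' Rotation carrying one frame to the next segment's frame
#'
#' Evaluates `exp(U * ds)` in closed form (Rodrigues' formula), the rotation
#' by angle `kappa * ds` taking the frame at segment `n` to that at `n + 1`.
#' Returns the identity for a straight segment (`kappa = 0`).
#'
#' @inheritParams darboux_matrix
#' @param ds Segment arc-length (> 0).
#' @return A 3x3 rotation matrix.
#' @export
segment_rotation <- function(kappa1, kappa2, ds) {
  stopifnot(ds > 0)
  k2 <- kappa1^2 + kappa2^2
  if (k2 == 0) return(diag(3))
  k <- sqrt(k2)
  U <- darboux_matrix(kappa1, kappa2)
  th <- k * ds
  if (th < 1e-6) {
    a <- ds * (1 - th^2 / 6)
    b <- 0.5 * ds^2 * (1 - th^2 / 12)
  } else {
    a <- sin(th) / k
    b <- (1 - cos(th)) / k2
  }
  diag(3) + a * U + b * (U %*% U)
}

#' Reconstruct frames and positions from curvature components
#'
#' Cumulatively applies the per-segment rotations starting from the base
#' frame and integrates the tangent to recover the centerline: the position
#' sequence is the running sum of `T * ds` from the base (so positions are
#' segment endpoints, `N + 1` of them including the base).
#'
#' @param state An [organ_state()].
#' @return A list with `m1`, `m2`, `tangent` (`N` x 3 matrices; the frame of
#'   segment `n` is attached at its base-side endpoint) and `positions`
#'   (`(N+1)` x 3 matrix starting at `base_position`).
#' @export
propagate_frames <- function(state) {
  stopifnot(inherits(state, "organ_state"))
  propagate_frames_cpp(state$kappa1, state$kappa2, state$ds,
                       state$base_frame, state$base_position)
}

#' Assemble the 3x3 frame of one segment from propagated rows
#'
#' @param frames Result of [propagate_frames()].
#' @param n Segment index (1-based).
#' @return 3x3 matrix with rows `(m1, m2, T)`.
#' @export
frame_at <- function(frames, n) {
  rbind(frames$m1[n, ], frames$m2[n, ], frames$tangent[n, ])
}

#' Frenet-Serret descriptors from natural-frame curvature components
#'
#' Converts the two natural-frame curvature components into total curvature
#' `kappa = sqrt(kappa1^2 + kappa2^2)`, the cross-sectional angle
#' `phi = atan2(kappa2, kappa1)` (unwrapped along the arc so that the torsion
#' is free of spurious 2*pi jumps), and the torsion `tau` as the backward
#' difference of `phi` over `ds`. Where `kappa = 0` the normal direction is
#' undefined, and both `phi` and `tau` are reported as `NA`.
#'
#' @param kappa1,kappa2 Numeric vectors of equal length.
#' @param ds Segment arc-length.
#' @return A list with numeric vectors `kappa`, `phi`, `tau`.
#' @export
frenet_from_natural <- function(kappa1, kappa2, ds) {
  stopifnot(length(kappa1) == length(kappa2), ds > 0)
  n <- length(kappa1)
  kappa <- sqrt(kappa1^2 + kappa2^2)
  phi <- rep(NA_real_, n)
  def <- kappa > 0
  phi[def] <- atan2(kappa2[def], kappa1[def])
  # unwrap the defined entries in order of arc-length
  idx <- which(def)
  if (length(idx) > 1) {
    ph <- phi[idx]
    d <- diff(ph)
    jumps <- round(d / (2 * pi))
    ph <- ph - c(0, cumsum(jumps)) * 2 * pi
    phi[idx] <- ph
  }
  tau <- rep(NA_real_, n)
  if (n > 1) {
    ok <- def[-1] & def[-n]
    tau[-1][ok] <- (phi[-1][ok] - phi[-n][ok]) / ds
  }
  list(kappa = kappa, phi = phi, tau = tau)
}

#' Write an organ state to a text file
#'
#' Serializes as a JSON header block (lines prefixed `#`) holding the scalar
#' fields and base frame, followed by a CSV table with columns `n`, `kappa1`,
#' `kappa2`. Doubles are written with 17 significant digits so that a
#' write-read round trip is bit-exact.
#'
#' @param state An [organ_state()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_organ_state()]
#' @export
write_organ_state <- function(state, path) {
  stopifnot(inherits(state, "organ_state"))
  header <- jsonlite::toJSON(
    list(ds = num17(state$ds), radius = num17(state$radius),
         growth_zone_length = num17(state$growth_zone_length),
         base_frame = vapply(as.vector(t(state$base_frame)), num17, ""),
         base_position = vapply(state$base_position, num17, "")),
    auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines("n,kappa1,kappa2", con)
  writeLines(sprintf("%d,%s,%s", seq_len(state$n_segments),
                     vapply(state$kappa1, num17, ""),
                     vapply(state$kappa2, num17, "")), con)
  invisible(path)
}

#' Read an organ state written by [write_organ_state()]
#'
#' @param path File path.
#' @return An [organ_state()].
#' @export
read_organ_state <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  tab <- utils::read.csv(text = lines[-1])
  organ_state(kappa1 = tab$kappa1, kappa2 = tab$kappa2,
              ds = as.numeric(hdr$ds), radius = as.numeric(hdr$radius),
              growth_zone_length = as.numeric(hdr$growth_zone_length),
              base_frame = matrix(as.numeric(hdr$base_frame), 3, 3,
                                  byrow = TRUE),
              base_position = as.numeric(hdr$base_position))
}

# full-precision decimal form of a double (round-trips exactly)
num17 <- function(x) sprintf("%.17g", x)
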