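#' Stimulus vector fields
#'
#' A stimulus is a vector field `I(r) * n(r)` sensed by the organ: a magnitude
#' and a unit direction at every point in space. Three geometries are
#' provided:
#' * `stimulus_constant()` — a parallel field from an infinitely distant
#'   source (sunlight, gravity): direction and magnitude constant in space.
#' * `stimulus_point()` — a radial field from a point source at `source`
#'   (a nearby lamp, a water source): direction from the queried position
#'   toward the source.
#' * `stimulus_line()` — an attracting line (a support to twine around):
#'   direction from the queried position toward the nearest point on the
#'   line through `base` along `axis`.
#'
#' `magnitude` is either a single non-negative number or a function of the
#' distance to the source (point/line kinds) or of the position matrix
#' (constant kind), allowing e.g. a diffusive chemical profile.
#'
#' @param direction,axis Numeric 3-vector; normalized internally.
#' @param source,base Numeric 3-vector.
#' @param magnitude Non-negative scalar, or a function as described above.
#' @param min_distance Point kind only: querying closer than this to the
#'   source is a degenerate-source error (the direction is undefined there).
#' @return An object of class `stimulus_field`.
#' @name stimulus_field
NULL

#' @rdname stimulus_field
#' @export
stimulus_constant <- function(direction, magnitude = 1) {
  structure(list(kind = "constant", direction = unitize(direction),
                 magnitude = magnitude), class = "stimulus_field")
}

#' @rdname stimulus_field
#' @export
stimulus_point <- function(source, magnitude = 1, min_distance = 1e-11) {
  structure(list(kind = "point", source = as.numeric(source),
                 magnitude = magnitude, min_distance = min_distance),
            class = "stimulus_field")
}

#' @rdname stimulus_field
#' @export
stimulus_line <- function(base, axis, magnitude = 1) {
  structure(list(kind = "line", base = as.numeric(base),
                 axis = unitize(axis), magnitude = magnitude),
            class = "stimulus_field")
}

unitize <- function(v) {
  v <- as.numeric(v)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero direction vector", call. = FALSE)
  v / nv
}

#' Evaluate a stimulus field at a set of positions
#'
#' @param field A [stimulus_field].
#' @param positions `n` x 3 matrix of query positions.
#' @return List with `direction` (`n` x 3, unit rows; zero rows where the
#'   direction is undefined, i.e. on a line stimulus axis) and `magnitude`
#'   (length-`n` vector).
#' @export
eval_stimulus <- function(field, positions) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  if (field$kind == "constant") {
    dir <- matrix(field$direction, n, 3, byrow = TRUE)
    mag <- if (is.function(field$magnitude)) field$magnitude(positions)
           else rep(field$magnitude, n)
  } else if (field$kind == "point") {
    d <- sweep(-positions, 2, field$source, "+")   # source - position
    dist <- sqrt(rowSums(d^2))
    if (any(dist < field$min_distance))
      stop("degenerate point source: query position coincides with the source",
           call. = FALSE)
    dir <- d / dist
    mag <- if (is.function(field$magnitude)) field$magnitude(dist)
           else rep(field$magnitude, n)
  } else if (field$kind == "line") {
    rho <- line_displacement_rows(positions, field$base, field$axis)
    dist <- sqrt(rowSums(rho^2))
    dir <- matrix(0, n, 3)
    ok <- dist > 0
    dir[ok, ] <- -rho[ok, , drop = FALSE] / dist[ok]
    mag <- if (is.function(field$magnitude)) field$magnitude(dist)
           else rep(field$magnitude, n)
  } else stop("unknown stimulus kind: ", field$kind, call. = FALSE)
  if (any(mag < 0)) stop("stimulus magnitude must be >= 0", call. = FALSE)
  list(direction = dir, magnitude = mag)
}

#' Sensitivity (gain) functions mapping stimulus intensity to response
#'
#' Biophysical sensory laws `lambda(I)`:
#' * `sensitivity_constant(lambda0)` — intensity-independent response, as
#'   found for gravitropism (only inclination is sensed).
#' * `sensitivity_weber_fechner(a, b, I0)` — logarithmic law
#'   `lambda(I) = a + b * log(I / I0)`.
#' * `sensitivity_stevens(a, b)` — power law `lambda(I) = a * I^b`, as found
#'   for phototropism. With `b = 1` the response is linear in the sensed
#'   perpendicular intensity.
#'
#' @param lambda0,a,b,I0 Law parameters.
#' @return An object of class `sensitivity_function`, callable on a numeric
#'   vector of intensities.
#' @name sensitivity_function
NULL

#' @rdname sensitivity_function
#' @export
sensitivity_constant <- function(lambda0) {
  f <- function(I) rep(lambda0, length(I))
  structure(f, law = "constant", params = list(lambda0 = lambda0),
            class = c("sensitivity_function", "function"))
}

#' @rdname sensitivity_function
#' @export
sensitivity_weber_fechner <- function(a, b, I0) {
  f <- function(I) a + b * log(I / I0)
  structure(f, law = "weber_fechner", params = list(a = a, b = b, I0 = I0),
            class = c("sensitivity_function", "function"))
}

#' @rdname sensitivity_function
#' @export
sensitivity_stevens <- function(a, b) {
  f <- function(I) a * I^b
  structure(f, law = "stevens", params = list(a = a, b = b),
            class = c("sensitivity_function", "function"))
}

#' Component of a signal perpendicular to the organ surface
#'
#' The cross-section of a cylindrical organ only senses the projection of a
#' stimulus perpendicular to its tangent: `I_perp = T x (I x T)`, of magnitude
#' `|I| sin(theta)` with `theta` the angle between tangent and signal.
#'
#' @param signal Numeric 3-vector.
#' @param tangent Unit 3-vector.
#' @return Numeric 3-vector orthogonal to `tangent`.
#' @export
perpendicular_component <- function(signal, tangent) {
  signal <- as.numeric(signal); tangent <- as.numeric(tangent)
  stopifnot(abs(sum(tangent^2) - 1) < 1e-8)
  signal - sum(signal * tangent) * tangent
}

#' Local response vector to a stimulus
#'
#' Evaluates the field at `position`, projects it perpendicular to `tangent`,
#' applies the sensitivity law to the perpendicular intensity `I_perp`, and
#' returns `-lambda(I_perp) * n_perp` (the conventional minus sign; scenario
#' builders own the attract/repel sign, see [build_scenario()]). Returns the
#' zero vector when the signal is parallel to the tangent (`I_perp = 0`): no
#' directional information is sensed.
#'
#' @param field A [stimulus_field].
#' @param sens A [sensitivity_function].
#' @param position Numeric 3-vector.
#' @param tangent Unit 3-vector.
#' @return Numeric 3-vector in the cross-section plane.
#' @export
response_vector <- function(field, sens, position, tangent) {
  ev <- eval_stimulus(field, matrix(position, 1, 3))
  sig <- ev$magnitude[1] * ev$direction[1, ]
  perp <- perpendicular_component(sig, tangent)
  I_perp <- sqrt(sum(perp^2))
  if (I_perp == 0) return(c(0, 0, 0))
  -sens(I_perp) * perp / I_perp
}

#' Shortest displacement from a line to a point
#'
#' For a line through `line_base` along unit `direction`, returns
#' `rho = (r - base) - direction * ((r - base) . direction)`, the vector from
#' the nearest point on the line to `position`; orthogonal to the line.
#'
#' @param position Numeric 3-vector.
#' @param line_base Numeric 3-vector on the line.
#' @param direction Unit 3-vector along the line.
#' @return Numeric 3-vector (zero when `position` lies on the line; its
#'   direction is then undefined and callers must handle it).
#' @export
line_displacement <- function(position, line_base, direction) {
  direction <- as.numeric(direction)
  stopifnot(abs(sum(direction^2) - 1) < 1e-8)
  d <- as.numeric(position) - as.numeric(line_base)
  d - direction * sum(d * direction)
}

line_displacement_rows <- function(positions, line_base, direction) {
  d <- sweep(positions, 2, as.numeric(line_base))
  proj <- as.vector(d %*% direction)
  d - outer(proj, direction)
}

#' Transport an apical response to a local cross-section
#'
#' With apical sensing, the whole organ responds to what is sensed at the tip
#' alone: the apex response is decomposed into its cross-sectional components
#' `(r . m1(L), r . m2(L))` in the apex frame, and a vector with the same
#' components is rebuilt in the local frame. On a straight organ (all frames
#' equal) this reduces to the identity, so apical and local sensing coincide
#' for a constant stimulus.
#'
#' @param apex_response Numeric 3-vector sensed at the tip.
#' @param apex_frame,local_frame 3x3 frames with rows `(m1, m2, T)`.
#' @return Numeric 3-vector in the local cross-section plane.
#' @export
apical_broadcast <- function(apex_response, apex_frame, local_frame) {
  c1 <- sum(apex_response * apex_frame[1, ])
  c2 <- sum(apex_response * apex_frame[2, ])
  c1 * local_frame[1, ] + c2 * local_frame[2, ]
}
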