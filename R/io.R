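#' Load a simulation configuration from a file and/or overrides
#'
#' Reads an optional YAML file of configuration keys (any subset of the
#' [sim_config()] arguments), applies overrides, and returns the fully
#' resolved, validated configuration. Unknown keys are rejected with the
#' nearest valid key named in the message; the grid constraint
#' `ds = Lgz * E * dt` is enforced.
#'
#' @param path Optional path to a YAML config file.
#' @param overrides Optional overrides: a named list, or a character vector
#'   of `"key=value"` strings (as from a command line).
#' @return A validated [sim_config()].
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  args <- list()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read config files",
           call. = FALSE)
    args <- yaml::read_yaml(path)
    if (is.null(args)) args <- list()
  }
  if (is.character(overrides)) {
    kv <- strsplit(overrides, "=", fixed = TRUE)
    overrides <- stats::setNames(
      lapply(kv, function(p) parse_config_value(paste(p[-1], collapse = "="))),
      vapply(kv, `[[`, "", 1))
  }
  for (k in names(overrides)) args[[k]] <- overrides[[k]]
  valid <- names(formals(sim_config))
  bad <- setdiff(names(args), valid)
  if (length(bad)) {
    near <- vapply(bad, function(b) {
      d <- utils::adist(b, valid)
      valid[which.min(d)]
    }, "")
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", bad, near),
               collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, args)
}

parse_config_value <- function(x) {
  num <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
  if (!anyNA(num)) return(num)
  if (x %in% c("TRUE", "FALSE", "true", "false")) return(toupper(x) == "TRUE")
  x
}

trajectory_columns <- c("step", "time", "n", "x", "y", "z",
                        "kappa1", "kappa2", "kappa", "phi", "tau")

#' Write a trajectory to CSV with a JSON manifest sidecar
#'
#' One row per (recorded step, segment) with columns `step`, `time`, `n`,
#' `x`, `y`, `z` (segment endpoint), `kappa1`, `kappa2`, `kappa`, `phi`,
#' `tau`. Numeric fields carry 17 significant digits so a read-back
#' reproduces values bit-exactly. The manifest (`<path>.manifest.json`) is
#' always written alongside and holds the fully resolved configuration, the
#' package version, the column schema and an MD5 checksum of the CSV — it
#' suffices to reproduce the run bit-identically.
#'
#' @param record A `growth_trajectory` from [grow_sim()].
#' @param path Output CSV path.
#' @return The manifest, invisibly (also written as JSON).
#' @export
write_trajectory <- function(record, path) {
  stopifnot(inherits(record, "growth_trajectory"),
            length(record$states) > 0)
  nrows <- sum(vapply(record$states, function(s) s$n_segments, 0L))
  lines <- character(length(record$states))
  for (i in seq_along(record$states)) {
    st <- record$states[[i]]
    fr <- propagate_frames(st)
    n <- st$n_segments
    pos <- fr$positions[-1, , drop = FALSE]   # tip-side endpoints
    step <- as.integer(round(record$times[i] / record$config$dt))
    lines[i] <- paste(sprintf(
      "%d,%s,%d,%s,%s,%s,%s,%s,%s,%s,%s",
      step, num17(record$times[i]), seq_len(n),
      vapply(pos[, 1], num17, ""), vapply(pos[, 2], num17, ""),
      vapply(pos[, 3], num17, ""),
      vapply(st$kappa1, num17, ""), vapply(st$kappa2, num17, ""),
      vapply(record$kappa[[i]], num17, ""),
      vapply(record$phi[[i]], num17na, ""),
      vapply(record$tau[[i]], num17na, "")), collapse = "\n")
  }
  con <- file(path, "w")
  writeLines(paste(trajectory_columns, collapse = ","), con)
  writeLines(lines, con)
  close(con)

  manifest <- list(
    format = "growrod-trajectory-csv",
    package_version = as.character(utils::packageVersion("growrod")),
    columns = trajectory_columns,
    units = "dimensionless model units",
    config = resolve_config_list(record$config),
    n_recorded_steps = length(record$states),
    n_rows = nrows,
    converged = isTRUE(record$converged),
    checksum_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

manifest_path <- function(path) paste0(path, ".manifest.json")

num17na <- function(x) if (is.na(x)) "NA" else sprintf("%.17g", x)

resolve_config_list <- function(config) {
  cfg <- unclass(config)
  cfg$custom_spec <- if (is.null(cfg$custom_spec)) NULL else "custom"
  cfg[!vapply(cfg, is.null, TRUE)]
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A data frame with the documented columns.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, colClasses = c(step = "integer", n = "integer"))
}

#' Render a 3D snapshot of an organ
#'
#' Static orthographic rendering of the centerline: the sub-apical growth
#' zone in green, the mature region in gray, and the apex triad drawn as
#' arrows (tangent red, normal blue, bi-normal green; the normal is omitted
#' where the curvature vanishes). An optional history polyline (e.g. the
#' trace of the tip normal) is drawn in blue.
#'
#' @param state An [organ_state()].
#' @param frames Result of [propagate_frames()] for `state` (computed if
#'   missing).
#' @param path Optional output PNG path; if `NULL`, draws on the current
#'   device.
#' @param n_history Optional matrix of 3D points drawn as a blue polyline.
#' @param azimuth,elevation View angles in degrees.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_snapshot <- function(state, frames = NULL, path = NULL,
                          n_history = NULL, azimuth = 30, elevation = 20) {
  stopifnot(inherits(state, "organ_state"))
  if (is.null(frames)) frames <- propagate_frames(state)
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  az <- azimuth * pi / 180; el <- elevation * pi / 180
  proj <- function(p) {
    p <- matrix(p, ncol = 3)
    cbind(-sin(az) * p[, 1] + cos(az) * p[, 2],
          -cos(az) * sin(el) * p[, 1] - sin(az) * sin(el) * p[, 2] +
            cos(el) * p[, 3])
  }
  pos <- frames$positions
  n <- state$n_segments
  n_gz <- min(n, ceiling(state$growth_zone_length / state$ds))
  pts <- proj(pos)
  extra <- if (is.null(n_history)) NULL else
    proj(n_history[stats::complete.cases(n_history), , drop = FALSE])
  xl <- range(c(pts[, 1], extra[, 1])); yl <- range(c(pts[, 2], extra[, 2]))
  pad <- 0.25 * max(diff(xl), diff(yl), 1e-3)
  graphics::plot(NA, xlim = xl + c(-pad, pad), ylim = yl + c(-pad, pad),
                 asp = 1, xlab = "", ylab = "", axes = FALSE)
  mature <- n - n_gz
  if (mature > 0)
    graphics::lines(pts[1:(mature + 1), , drop = FALSE], col = "gray40",
                    lwd = 4)
  graphics::lines(pts[(mature + 1):(n + 1), , drop = FALSE],
                  col = "forestgreen", lwd = 4)
  if (!is.null(extra) && nrow(extra) > 1)
    graphics::lines(extra, col = "blue", lwd = 1)

  tip <- pos[n + 1, ]
  alen <- 0.2 * max(n * state$ds, 1e-3)
  tangent <- frames$tangent[n, ]
  fs <- frenet_from_natural(state$kappa1[n], state$kappa2[n], state$ds)
  draw_arrow <- function(v, col) {
    seg <- proj(rbind(tip, tip + alen * v))
    graphics::arrows(seg[1, 1], seg[1, 2], seg[2, 1], seg[2, 2],
                     col = col, lwd = 2, length = 0.1)
  }
  draw_arrow(tangent, "red")
  if (is.finite(fs$phi[1])) {
    normal <- cos(fs$phi[1]) * frames$m1[n, ] + sin(fs$phi[1]) * frames$m2[n, ]
    binormal <- c(tangent[2] * normal[3] - tangent[3] * normal[2],
                  tangent[3] * normal[1] - tangent[1] * normal[3],
                  tangent[1] * normal[2] - tangent[2] * normal[1])
    draw_arrow(normal, "blue")
    draw_arrow(binormal, "forestgreen")
  }
  invisible(path)
}
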