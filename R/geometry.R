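# Stepping geometry: foot-placement trials, derived control variables, file I/O.
#
# Coordinate convention: +z is lateral, chosen so that z_R > z_L in normal
# (non-crossover) stance, hence step width w = z_R - z_L > 0 for ordinary
# steps.  The origin is the geometric center of the walking path.  Crossover
# steps (w < 0) are representable; w is signed throughout.  All quantities
# are in meters.

#' Construct a foot-placement trial
#'
#' A trial is the per-step record of lateral foot placements during walking:
#' the left (`z_L`) and right (`z_R`) lateral positions at each step, plus
#' which foot was newly placed on that step.  Steps are indexed 0...N-1; the
#' foot not placed on a given step is carried over from the previous step.
#'
#' @param z_L numeric vector, lateral left-foot placement per step (m).
#' @param z_R numeric vector, lateral right-foot placement per step (m),
#'   same length as `z_L`.
#' @param placed_side character vector of `"L"`/`"R"`, which foot was newly
#'   placed at each step; must strictly alternate.
#' @param meta optional named list of provenance (seed, model, flags, ...).
#' @return An object of class `foot_placement_trial`: a list with fields
#'   `step` (0-based index), `z_L`, `z_R`, `placed_side`, `meta`.
#' @examples
#' tr <- foot_placement_trial(c(-0.1, -0.1), c(0.1, 0.12), c("R", "L"))
#' derive_state_series(tr)
#' @export
foot_placement_trial <- function(z_L, z_R, placed_side, meta = list()) {
  z_L <- as.numeric(z_L)
  z_R <- as.numeric(z_R)
  placed_side <- as.character(placed_side)
  n <- length(z_L)
  if (length(z_R) != n)
    stop("z_L and z_R must have equal length (got ", n, " and ", length(z_R), ")")
  if (n < 2L)
    stop("a trial needs at least 2 steps, got ", n)
  if (length(placed_side) != n)
    stop("placed_side must have one entry per step")
  bad <- which(!is.finite(z_L))
  if (length(bad))
    stop("non-finite z_L at step ", bad[1L] - 1L)
  bad <- which(!is.finite(z_R))
  if (length(bad))
    stop("non-finite z_R at step ", bad[1L] - 1L)
  if (!all(placed_side %in% c("L", "R")))
    stop("placed_side entries must be \"L\" or \"R\"")
  same <- which(placed_side[-1L] == placed_side[-n])
  if (length(same))
    stop("placed_side must alternate between consecutive steps; ",
         "steps ", same[1L] - 1L, " and ", same[1L],
         " are both \"", placed_side[same[1L]], "\"")
  structure(
    list(step = seq_len(n) - 1L, z_L = z_L, z_R = z_R,
         placed_side = placed_side, meta = meta),
    class = "foot_placement_trial"
  )
}

#' @export
print.foot_placement_trial <- function(x, ...) {
  n <- length(x$z_L)
  cat("<foot_placement_trial> ", n, " steps\n", sep = "")
  cat("  z_L: [", format(min(x$z_L), digits = 4), ", ",
      format(max(x$z_L), digits = 4), "] m\n", sep = "")
  cat("  z_R: [", format(min(x$z_R), digits = 4), ", ",
      format(max(x$z_R), digits = 4), "] m\n", sep = "")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of steps in a trial
#' @param trial a `foot_placement_trial`.
#' @return integer step count N.
#' @export
n_steps <- function(trial) length(trial$z_L)

#' Derive the regulated stepping variables from foot placements
#'
#' Maps the per-step foot placements to the three biomechanically relevant
#' control variables: lateral body position `z_B` (midpoint of the feet,
#' a proxy for center-of-mass position), heading `dz_B` (its first
#' difference, a proxy for lateral speed), and step width `w` (right minus
#' left foot).  `dz_B` is undefined at step 0 and has length N-1.
#'
#' @param trial a `foot_placement_trial`.
#' @return An object of class `state_series`: list with `z_B` (length N),
#'   `dz_B` (length N-1), `w` (length N), all in meters.
#' @examples
#' tr <- foot_placement_trial(c(-0.1, -0.1), c(0.1, 0.12), c("R", "L"))
#' s <- derive_state_series(tr)
#' s$w   # 0.20 0.22
#' @export
derive_state_series <- function(trial) {
  stopifnot(inherits(trial, "foot_placement_trial"))
  z_B <- (trial$z_L + trial$z_R) / 2
  w <- trial$z_R - trial$z_L
  dz_B <- diff(z_B)
  structure(list(z_B = z_B, dz_B = dz_B, w = w), class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat("<state_series> N =", length(x$z_B), "\n")
  cat("  sd(z_B) =", format(stats::sd(x$z_B), digits = 4),
      " sd(dz_B) =", format(stats::sd(x$dz_B), digits = 4),
      " sd(w) =", format(stats::sd(x$w), digits = 4), "\n")
  invisible(x)
}

#' Recover foot placements from body position and step width
#'
#' The inverse of the (`z_B`, `w`) map: `z_L = z_B - w/2`,
#' `z_R = z_B + w/2`.  Together with [derive_state_series()] this is an
#' exact (bit-level) inverse pair, since both directions use the same
#' binary halving.
#'
#' @param z_B lateral body position (m), scalar or vector.
#' @param w step width (m), same length.
#' @return list with numeric `z_L`, `z_R`.
#' @examples
#' feet_from_state(0, 0.2)  # z_L = -0.1, z_R = 0.1
#' @export
feet_from_state <- function(z_B, w) {
  if (!all(is.finite(z_B)) || !all(is.finite(w)))
    stop("z_B and w must be finite")
  list(z_L = z_B - w / 2, z_R = z_B + w / 2)
}

#' Write a trial to a delimited text file
#'
#' Format: comma-separated with header `step,side,z_L,z_R`, one row per
#' step, placements in meters.  Values are written with 17 significant
#' digits so the write/read round trip is lossless for doubles.
#'
#' @param trial a `foot_placement_trial`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @seealso [read_trial()]
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "foot_placement_trial"))
  lines <- c("step,side,z_L,z_R",
             sprintf("%d,%s,%.17g,%.17g",
                     trial$step, trial$placed_side, trial$z_L, trial$z_R))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trial from a delimited text file
#'
#' @param path file written by [write_trial()] (or any file with columns
#'   `step`, `side`, `z_L`, `z_R`).
#' @param meta optional metadata list attached to the trial.
#' @return a `foot_placement_trial`.
#' @export
read_trial <- function(path, meta = list()) {
  if (!file.exists(path))
    stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = c(side = "character"))
  required <- c("step", "side", "z_L", "z_R")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trial file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$z_L) | !is.finite(df$z_R))
  if (length(bad))
    stop("malformed or non-finite placement at row ", bad[1L])
  foot_placement_trial(df$z_L, df$z_R, df$side, meta = meta)
}

#' Write derived state series to a delimited text file
#'
#' Format: `step,z_B,dz_B,w`; `dz_B` is blank on row 0 (undefined there).
#'
#' @param series a `state_series`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_state_series <- function(series, path) {
  stopifnot(inherits(series, "state_series"))
  n <- length(series$z_B)
  dz <- c("", sprintf("%.17g", series$dz_B))
  lines <- c("step,z_B,dz_B,w",
             sprintf("%d,%.17g,%s,%.17g",
                     seq_len(n) - 1L, series$z_B, dz, series$w))
  writeLines(lines, path)
  invisible(path)
}
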