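# Model-selection experiments: parameter sweeps over the multi-objective
# mixing weight and noise/cost variants, the mean +/- 1 SD reference-band
# comparison rule, and a synthetic reference fixture emulating the human
# treadmill dataset.

# Measures aggregated per sweep condition.
.MEASURE_COLS <- c("sd_zB", "sd_dzB", "sd_w",
                   "alpha_zB", "alpha_dzB", "alpha_w",
                   "slope_zB", "slope_dzB", "slope_w",
                   "r2_zB", "r2_dzB", "r2_w",
                   "sd_zL", "sd_zR", "alpha_zL", "alpha_zR")

#' Default sweep grid for the position-step-width model
#'
#' Mixing weights `rho` from 0.89 to 0.97 in steps of 0.02, crossed with
#' five parameter variants: baseline, effort-cost ratios 0 and 0.2, and
#' additive noise scaled by 0.9 and 1.1.
#'
#' @return `data.frame` with columns `rho`, `gamma_over_alpha`,
#'   `sigma_a_scale`, `variant`.
#' @export
default_sweep_grid <- function() {
  rho <- seq(0.89, 0.97, by = 0.02)
  variants <- data.frame(
    variant = c("baseline", "ga0", "ga0.2", "sa0.9", "sa1.1"),
    gamma_over_alpha = c(0.1, 0, 0.2, 0.1, 0.1),
    sigma_a_scale = c(1, 1, 1, 0.9, 1.1),
    stringsAsFactors = FALSE)
  grid <- merge(data.frame(rho = rho), variants)
  grid[order(grid$variant, grid$rho),
       c("rho", "gamma_over_alpha", "sigma_a_scale", "variant")]
}

# Build the two regulator specs for one grid row from base specs.
.condition_specs <- function(row, base1, base2) {
  adjust <- function(sp) {
    sa <- sp$sigma_a * row$sigma_a_scale
    regulator_spec(sp$variable, q_star = sp$q_star, sigma_a = sa,
                   sigma_m = 0.1 * sa,
                   gamma_over_alpha = row$gamma_over_alpha, g = sp$g)
  }
  multi_objective_spec(adjust(base1), adjust(base2), rho = row$rho)
}

#' Run a parameter sweep of the multi-objective model
#'
#' For every grid condition, simulates `config$n_trials` trials,
#' summarizes each ([summarize_trial()]), and aggregates the mean and 95%
#' confidence interval (mean +/- 1.96 SEM across trials) of every
#' measure.  Constraint-violation percentages are computed on the
#' *unconstrained* twin of each condition (same seeds, constraints not
#' enforced) as a feasibility diagnostic, and on the condition itself.
#'
#' @param grid `data.frame` with columns `rho`, `gamma_over_alpha`,
#'   `sigma_a_scale` (and optionally `variant`); see
#'   [default_sweep_grid()].
#' @param base1,base2 [regulator_spec()]s for the two objectives at
#'   baseline; grid columns override `gamma_over_alpha` and scale
#'   `sigma_a` (with `sigma_m = 0.1 * sigma_a` maintained).
#' @param config a [simulation_config()]; trial `t` of condition `i` uses
#'   seed `config$seed + 1000 * i + t`, so the whole table is
#'   reproducible from one seed.
#' @param constraints a [constraint_spec()].
#' @param summaries if `FALSE`, skip the per-trial summary statistics and
#'   report only violation percentages (fast feasibility scan).
#' @return `data.frame`, one row per condition: the grid columns, then
#'   `<measure>_mean` and `<measure>_ci` for each summary measure, then
#'   `pct_boundary`/`pct_width` (condition as simulated) and
#'   `pct_boundary_unconstrained`/`pct_width_unconstrained`.
#' @export
run_parameter_sweep <- function(grid = default_sweep_grid(),
                                base1 = regulator_spec("z_B"),
                                base2 = regulator_spec("w"),
                                config = simulation_config(),
                                constraints = constraint_spec(),
                                summaries = TRUE) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0,
            all(c("rho", "gamma_over_alpha", "sigma_a_scale") %in% names(grid)))
  uncon <- unconstrained(constraints)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mspec <- .condition_specs(grid[i, ], base1, base2)
    stats_list <- vector("list", config$n_trials)
    viol <- matrix(0, config$n_trials, 4L)
    for (t in seq_len(config$n_trials)) {
      cfg_t <- simulation_config(config$n_steps, 1L,
                                 seed = config$seed + 1000L * i + t,
                                 first_swing = config$first_swing,
                                 z_B0 = config$z_B0, w0 = config$w0)
      tr <- simulate_multi_objective(mspec, cfg_t, constraints)
      tr_u <- simulate_multi_objective(mspec, cfg_t, uncon)
      v <- violation_rates(tr, constraints)
      v_u <- violation_rates(tr_u, constraints)
      viol[t, ] <- c(v$pct_boundary, v$pct_width,
                     v_u$pct_boundary, v_u$pct_width)
      if (summaries) stats_list[[t]] <- summarize_trial(tr)
    }
    row <- grid[i, , drop = FALSE]
    if (summaries) {
      stats <- do.call(rbind, stats_list)
      for (m in .MEASURE_COLS) {
        x <- stats[[m]]
        row[[paste0(m, "_mean")]] <- mean(x, na.rm = TRUE)
        row[[paste0(m, "_ci")]] <-
          1.96 * stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
      }
    }
    row$pct_boundary <- mean(viol[, 1L])
    row$pct_width <- mean(viol[, 2L])
    row$pct_boundary_unconstrained <- mean(viol[, 3L])
    row$pct_width_unconstrained <- mean(viol[, 4L])
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference bands from analyzed trials
#'
#' The expected range of a measure is its mean +/- 1 SD across reference
#' trials (human data or the synthetic fixture).
#'
#' @param stats `data.frame` of per-trial summary statistics (rows =
#'   trials, columns as produced by [summarize_trial()]).
#' @return An object of class `reference_bands`: `data.frame` with
#'   columns `measure`, `mean`, `sd`.
#' @export
reference_bands <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 2)
  cols <- intersect(.MEASURE_COLS, names(stats))
  if (!length(cols)) stop("no recognized measure columns in stats")
  out <- data.frame(
    measure = cols,
    mean = vapply(cols, function(m) mean(stats[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(cols, function(m) stats::sd(stats[[m]], na.rm = TRUE),
                numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("reference_bands", "data.frame")
  out
}

#' Compare a sweep condition to reference bands
#'
#' A model prediction is consistent with the reference whenever its mean
#' over simulated trials lies inside the reference mean +/- 1 SD band.
#'
#' @param row one row of a [run_parameter_sweep()] table (with
#'   `<measure>_mean` columns).
#' @param bands a [reference_bands()] object.
#' @param measures which measures to compare; default, all band measures
#'   present in `row`.
#' @return `data.frame` with columns `measure`, `sim_mean`, `band_mean`,
#'   `band_sd`, `pass`.
#' @export
compare_to_reference <- function(row, bands, measures = NULL) {
  stopifnot(inherits(bands, "reference_bands"))
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1)
    row <- as.list(row)
  }
  if (is.null(measures)) {
    measures <- bands$measure[paste0(bands$measure, "_mean") %in% names(row)]
  }
  missing <- setdiff(measures, bands$measure)
  if (length(missing))
    stop("reference bands missing measure(s): ",
         paste(missing, collapse = ", "))
  missing <- measures[!paste0(measures, "_mean") %in% names(row)]
  if (length(missing))
    stop("sweep row missing measure(s): ", paste(missing, collapse = ", "))
  idx <- match(measures, bands$measure)
  sim <- vapply(measures, function(m) as.numeric(row[[paste0(m, "_mean")]]),
                numeric(1))
  out <- data.frame(
    measure = measures,
    sim_mean = sim,
    band_mean = bands$mean[idx],
    band_sd = bands$sd[idx],
    stringsAsFactors = FALSE)
  out$pass <- abs(out$sim_mean - out$band_mean) <= out$band_sd
  rownames(out) <- NULL
  out
}

#' Generate the synthetic human-reference fixture
#'
#' Emulates the structure of the experimental dataset (65 treadmill trials
#' of 290 steps: 13 participants x 5 trials) by simulating the constrained
#' multi-objective position-step-width model at `rho = 0.93` and baseline
#' parameters -- the configuration that reproduces human stepping
#' dynamics: step width near 0.127 m with SD near 0.026 m, strongly
#' persistent lateral position, weakly persistent step width,
#' anti-persistent heading.  This fixture is synthetic: it stands in for
#' the human recordings when they are not available, and carries the
#' model's dynamics, not a participant's.
#'
#' @param seed integer seed; trial `t` uses seed `seed + t`.
#' @param n_trials number of trials (default 65).
#' @param n_steps steps per trial (default 290).
#' @param out_dir optional directory: writes one `fixture_trial_###.csv`
#'   per trial, `fixture_stats.csv`, and `fixture_bands.csv`.
#' @return list with `trials` (list of [foot_placement_trial()]),
#'   `stats` (per-trial summary `data.frame`), and `bands`
#'   ([reference_bands()]).
#' @export
generate_reference_fixture <- function(seed, n_trials = 65, n_steps = 290,
                                       out_dir = NULL) {
  mspec <- multi_objective_spec(regulator_spec("z_B"), regulator_spec("w"),
                                rho = 0.93)
  constraints <- constraint_spec()
  trials <- vector("list", n_trials)
  stats_list <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    cfg <- simulation_config(n_steps = n_steps, n_trials = 1L,
                             seed = seed + t)
    trials[[t]] <- simulate_multi_objective(mspec, cfg, constraints)
    stats_list[[t]] <- summarize_trial(trials[[t]])
  }
  stats <- do.call(rbind, stats_list)
  bands <- reference_bands(stats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_len(n_trials))
      write_trial(trials[[t]],
                  file.path(out_dir, sprintf("fixture_trial_%03d.csv", t)))
    utils::write.csv(stats, file.path(out_dir, "fixture_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(bands),
                     file.path(out_dir, "fixture_bands.csv"),
                     row.names = FALSE)
  }
  list(trials = trials, stats = stats, bands = bands)
}
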