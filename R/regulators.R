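# Stochastic optimal step-to-step regulators of lateral stepping.
#
# Each regulator treats one stepping variable q in {z_B, dz_B, w} as the
# state of a 1D discrete map across steps,
#
#     q_{n+1} = q_n + g (1 + sigma_m nu_m) u(q_n) + sigma_a nu_a ,
#
# with the stochastically optimal single-step control input
#
#     u(q_n) = -[1 / (1 + sigma_m^2 + gamma/alpha)] (q_n - q*) ,
#
# i.e. proportional error feedback with effective gain G in (0, 1].
# G = 1 (no multiplicative noise, no effort cost) is the unbiased limit:
# full one-step error correction.  Multi-objective regulation runs two such
# controllers in parallel and places the swing foot at a weighted average
# of the two placements each would have chosen on its own.

.VARIABLES <- c("z_B", "dz_B", "w")

#' Specify a single-variable stepping regulator
#'
#' @param variable controlled variable: `"z_B"` (lateral body position),
#'   `"dz_B"` (heading), or `"w"` (step width).
#' @param q_star goal value (m).  Defaults: 0 for `z_B` and `dz_B`
#'   (path center, straight ahead), 0.127 m for `w` (typical human mean
#'   step width on a treadmill).
#' @param sigma_a additive motor-noise SD (m).  Default 0.025 m, of the
#'   order of human step-width variability.
#' @param sigma_m multiplicative (signal-dependent) noise SD,
#'   dimensionless.  Default `0.1 * sigma_a` numerically.
#' @param gamma_over_alpha ratio of the effort-cost weight to the
#'   error-cost weight in the one-step cost
#'   `C = alpha * e^2 + gamma * u^2`; baseline 0.1.
#' @param g tuning gain multiplying the optimal control input; `g = 1`
#'   (default) leaves the derived optimum untouched.
#' @return An object of class `regulator_spec`.
#' @examples
#' regulator_spec("w")
#' regulator_spec("z_B", sigma_a = 0.03)
#' @export
regulator_spec <- function(variable = c("z_B", "dz_B", "w"),
                           q_star = NULL,
                           sigma_a = 0.025,
                           sigma_m = 0.1 * sigma_a,
                           gamma_over_alpha = 0.1,
                           g = 1) {
  variable <- match.arg(variable)
  if (is.null(q_star))
    q_star <- if (variable == "w") 0.127 else 0
  stopifnot(is.finite(q_star), is.finite(sigma_a), is.finite(sigma_m),
            is.finite(gamma_over_alpha), is.finite(g))
  if (sigma_a < 0) stop("sigma_a must be >= 0")
  if (sigma_m < 0) stop("sigma_m must be >= 0")
  if (gamma_over_alpha < 0) stop("gamma_over_alpha must be >= 0")
  if (g <= 0) stop("g must be > 0")
  structure(
    list(variable = variable, q_star = q_star, sigma_a = sigma_a,
         sigma_m = sigma_m, gamma_over_alpha = gamma_over_alpha, g = g),
    class = "regulator_spec"
  )
}

#' @export
print.regulator_spec <- function(x, ...) {
  cat("<regulator_spec> ", x$variable,
      ": q* = ", format(x$q_star),
      ", sigma_a = ", format(x$sigma_a),
      ", sigma_m = ", format(x$sigma_m),
      ", gamma/alpha = ", format(x$gamma_over_alpha),
      ", g = ", format(x$g),
      ", G = ", format(optimal_gain(x$sigma_m, x$gamma_over_alpha), digits = 5),
      "\n", sep = "")
  invisible(x)
}

#' Specify a two-objective stepping regulator
#'
#' Two independent single-variable controllers run in parallel; at each
#' step the swing foot is placed at the weighted average of the placements
#' the two would choose on their own: weight `1 - rho` on `spec1`'s
#' placement and `rho` on `spec2`'s.  By convention the headline
#' position-step-width model puts step width in `spec2`, so "93% step-width
#' control" is `rho = 0.93`.
#'
#' @param spec1,spec2 [regulator_spec()] objects for two *distinct*
#'   variables.
#' @param rho weight on `spec2`'s predicted placement, in `[0, 1]`.
#' @return An object of class `multi_objective_spec`.
#' @examples
#' multi_objective_spec(regulator_spec("z_B"), regulator_spec("w"), rho = 0.93)
#' @export
multi_objective_spec <- function(spec1, spec2, rho) {
  stopifnot(inherits(spec1, "regulator_spec"),
            inherits(spec2, "regulator_spec"))
  if (spec1$variable == spec2$variable)
    stop("spec1 and spec2 must regulate different variables")
  if (!is.finite(rho) || rho < 0 || rho > 1)
    stop("rho must be in [0, 1]")
  structure(list(spec1 = spec1, spec2 = spec2, rho = rho),
            class = "multi_objective_spec")
}

#' @export
print.multi_objective_spec <- function(x, ...) {
  cat("<multi_objective_spec> ",
      format(100 * (1 - x$rho)), "% ", x$spec1$variable, " / ",
      format(100 * x$rho), "% ", x$spec2$variable, " control\n", sep = "")
  invisible(x)
}

#' Specify biomechanical stepping constraints
#'
#' Lateral boundary and step-width limits used by constrained simulations.
#' Defaults reflect a 1.77 m wide treadmill (half-width 0.885 m) and a
#' step-width range of mean +/- 5 SD of human data, -0.15 cm to +25.54 cm
#' (slightly negative: narrow crossover steps are permitted).
#'
#' @param z_max lateral boundary half-width (m), > 0.
#' @param w_min,w_max step-width limits (m), `w_min < w_max`.
#' @param enforce if `TRUE`, simulations project infeasible placements onto
#'   the feasible interval; if `FALSE`, constraints are recorded but not
#'   enforced.
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(z_max = 0.885, w_min = -0.0015, w_max = 0.2554,
                            enforce = TRUE) {
  stopifnot(is.finite(z_max), is.finite(w_min), is.finite(w_max))
  if (z_max <= 0) stop("z_max must be > 0")
  if (w_min >= w_max) stop("w_min must be < w_max")
  structure(list(z_max = z_max, w_min = w_min, w_max = w_max,
                 enforce = isTRUE(enforce)),
            class = "constraint_spec")
}

#' Unconstrained twin of a constraint specification
#' @param constraints a `constraint_spec`.
#' @return the same limits with `enforce = FALSE`.
#' @export
unconstrained <- function(constraints) {
  stopifnot(inherits(constraints, "constraint_spec"))
  constraint_spec(constraints$z_max, constraints$w_min, constraints$w_max,
                  enforce = FALSE)
}

#' Specify a simulation run
#'
#' @param n_steps steps per trial (default 290, the analyzed trial length).
#' @param n_trials trials per condition (default 30).
#' @param seed integer RNG seed; all randomness flows from it.
#' @param first_swing which foot is newly placed at step 1 (`"L"` default).
#' @param z_B0 initial lateral body position (m); default 0 (path center).
#' @param w0 initial step width (m); default `NULL` means: the goal width
#'   `w*` of the width objective when one is simulated, else 0.127 m.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_steps = 290, n_trials = 30, seed = 1,
                              first_swing = c("L", "R"),
                              z_B0 = 0, w0 = NULL) {
  first_swing <- match.arg(first_swing)
  n_steps <- as.integer(n_steps)
  n_trials <- as.integer(n_trials)
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  stopifnot(is.finite(z_B0), is.null(w0) || is.finite(w0))
  structure(list(n_steps = n_steps, n_trials = n_trials,
                 seed = as.integer(seed), first_swing = first_swing,
                 z_B0 = z_B0, w0 = w0),
            class = "simulation_config")
}

#' Effective gain of the stochastically optimal controller
#'
#' `G = 1 / (1 + sigma_m^2 + gamma/alpha)`: the fraction of the current
#' goal-level error corrected at each step.  Strictly decreasing in both
#' arguments; `G = 1` iff both are zero (the unbiased
#' full-correction limit).
#'
#' @param sigma_m multiplicative noise SD (dimensionless), >= 0.
#' @param gamma_over_alpha effort/error cost-weight ratio, >= 0.
#' @return gain in (0, 1].
#' @examples
#' optimal_gain(0, 0)      # 1: unbiased proportional controller
#' optimal_gain(1, 0)      # 0.5
#' @export
optimal_gain <- function(sigma_m, gamma_over_alpha) {
  if (any(!is.finite(sigma_m)) || any(sigma_m < 0))
    stop("sigma_m must be finite and >= 0")
  if (any(!is.finite(gamma_over_alpha)) || any(gamma_over_alpha < 0))
    stop("gamma_over_alpha must be finite and >= 0")
  1 / (1 + sigma_m^2 + gamma_over_alpha)
}

#' Stochastically optimal control input
#'
#' `u = -G (q_n - q*)` with `G` from [optimal_gain()]: proportional
#' feedback on the current deviation from the goal.
#'
#' @param q_n current value of the controlled variable (m).
#' @param spec a [regulator_spec()].
#' @return control input `u` (m).
#' @export
control_input <- function(q_n, spec) {
  stopifnot(inherits(spec, "regulator_spec"), all(is.finite(q_n)))
  -optimal_gain(spec$sigma_m, spec$gamma_over_alpha) * (q_n - spec$q_star)
}

#' One step of the regulated 1D map
#'
#' `q_{n+1} = q_n + g (1 + sigma_m nu_m) u + sigma_a nu_a`, where `nu_m`
#' and `nu_a` are standard-normal draws from the seeded noise stream.
#'
#' @param q_n current state (m).
#' @param u control input (m), normally from [control_input()].
#' @param nu_m,nu_a standard-normal noise draws.
#' @param spec a [regulator_spec()].
#' @return next state `q_{n+1}` (m).
#' @export
state_update <- function(q_n, u, nu_m, nu_a, spec) {
  stopifnot(inherits(spec, "regulator_spec"))
  q_n + spec$g * (1 + spec$sigma_m * nu_m) * u + spec$sigma_a * nu_a
}

#' Swing-foot placement that realizes a target state value
#'
#' One foot is newly placed per step while the other is carried over.
#' Given the stance foot position, this inverts the stepping geometry to
#' find the unique swing-foot placement for which the resulting step
#' attains the controller's target value of the regulated variable.
#'
#' @param variable `"z_B"`, `"dz_B"`, or `"w"`.
#' @param q_target_next target value of that variable at the new step (m).
#' @param stance_z lateral position of the carried (stance) foot (m).
#' @param swing_side `"L"` or `"R"`: the foot being placed.
#' @param z_B_prev previous-step body position (m); required only for the
#'   heading variable.
#' @return swing-foot lateral placement (m).
#' @export
swing_foot_for_target <- function(variable, q_target_next, stance_z,
                                  swing_side, z_B_prev = NULL) {
  if (!swing_side %in% c("L", "R"))
    stop("swing_side must be \"L\" or \"R\"")
  switch(variable,
    w = if (swing_side == "L") stance_z - q_target_next
        else stance_z + q_target_next,
    z_B = 2 * q_target_next - stance_z,
    dz_B = {
      if (is.null(z_B_prev))
        stop("z_B_prev is required for heading control")
      2 * (z_B_prev + q_target_next) - stance_z
    },
    stop("unknown variable: ", variable)
  )
}

#' Project a candidate placement onto the feasible interval
#'
#' The feasible interval for the swing foot is the intersection of the
#' lateral boundary `[-z_max, +z_max]` with the interval implied by the
#' step-width limits given the stance foot.  The candidate is clamped to
#' the nearest point of that interval; flags record which limit bound the
#' clamp (both, when the binding endpoint is shared).
#'
#' @param z_candidate proposed swing-foot placement (m).
#' @param stance_z stance-foot position (m).
#' @param swing_side `"L"` or `"R"`.
#' @param constraints a [constraint_spec()]; with `enforce = FALSE` the
#'   candidate passes through unchanged.
#' @return list with `z_new`, `boundary_clamped`, `width_clamped`.
#' @export
clamp_to_constraints <- function(z_candidate, stance_z, swing_side,
                                 constraints) {
  stopifnot(inherits(constraints, "constraint_spec"))
  if (!constraints$enforce)
    return(list(z_new = z_candidate,
                boundary_clamped = FALSE, width_clamped = FALSE))
  if (swing_side == "L") {
    w_lo <- stance_z - constraints$w_max   # w = stance - z for a left step
    w_hi <- stance_z - constraints$w_min
  } else {
    w_lo <- stance_z + constraints$w_min   # w = z - stance for a right step
    w_hi <- stance_z + constraints$w_max
  }
  lo <- max(-constraints$z_max, w_lo)
  hi <- min(constraints$z_max, w_hi)
  if (lo > hi)
    stop("empty feasible interval: boundary and step-width limits are ",
         "inconsistent for stance foot at ", format(stance_z), " m")
  z_new <- min(max(z_candidate, lo), hi)
  boundary <- FALSE
  width <- FALSE
  if (z_new != z_candidate) {
    if (z_new == lo) {
      boundary <- -constraints$z_max >= w_lo
      width <- w_lo >= -constraints$z_max
    } else {
      boundary <- constraints$z_max <= w_hi
      width <- w_hi <= constraints$z_max
    }
  }
  list(z_new = z_new, boundary_clamped = boundary, width_clamped = width)
}

# Current value of the controlled variable read off the realized geometry.
# Heading is taken as 0 at the first transition (straight-ahead start);
# it is undefined at step 0.
.current_q <- function(variable, z_B, w, idx) {
  switch(variable,
    z_B = z_B[idx],
    w = w[idx],
    dz_B = if (idx == 1L) 0 else z_B[idx] - z_B[idx - 1L])
}

.resolve_w0 <- function(config, specs) {
  if (!is.null(config$w0)) return(config$w0)
  for (s in specs) if (s$variable == "w") return(s$q_star)
  0.127
}

#' Simulate a uni-objective stepping trial
#'
#' Runs the regulated 1D map for the controlled variable across
#' `config$n_steps` steps.  At each step, the controller proposes the next
#' value of its variable via [state_update()]; the alternating swing foot
#' is placed to realize it ([swing_foot_for_target()]), projected onto the
#' feasible interval when constraints are enforced; all other stepping
#' variables follow passively from geometry.  The value fed back to the
#' controller on the next step is the *realized* (post-clamp) one.
#'
#' @param spec a [regulator_spec()].
#' @param config a [simulation_config()]; `config$seed` determines the
#'   trial's noise stream (identical seed, identical trial).
#' @param constraints a [constraint_spec()].
#' @return a [foot_placement_trial()] with provenance in `$meta`
#'   (model, seed, clamp counts).
#' @examples
#' tr <- simulate_uni_objective(regulator_spec("w"),
#'                              simulation_config(n_steps = 50, seed = 7),
#'                              constraint_spec(enforce = FALSE))
#' summary(derive_state_series(tr)$w)
#' @export
simulate_uni_objective <- function(spec, config, constraints = constraint_spec()) {
  stopifnot(inherits(spec, "regulator_spec"),
            inherits(config, "simulation_config"),
            inherits(constraints, "constraint_spec"))
  n <- config$n_steps
  G <- optimal_gain(spec$sigma_m, spec$gamma_over_alpha)
  nu <- noise_stream(config$seed, spec$variable, n - 1L)

  z_L <- numeric(n); z_R <- numeric(n)
  w0 <- .resolve_w0(config, list(spec))
  feet <- feet_from_state(config$z_B0, w0)
  z_L[1L] <- feet$z_L; z_R[1L] <- feet$z_R
  z_B <- numeric(n); w <- numeric(n)
  z_B[1L] <- config$z_B0; w[1L] <- w0

  sides <- rep_len(if (config$first_swing == "L") c("L", "R") else c("R", "L"),
                   n - 1L)
  n_boundary <- 0L; n_width <- 0L
  for (i in 2:n) {
    s <- sides[i - 1L]
    stance <- if (s == "L") z_R[i - 1L] else z_L[i - 1L]
    q_n <- .current_q(spec$variable, z_B, w, i - 1L)
    u <- -G * (q_n - spec$q_star)
    q_next <- state_update(q_n, u, nu[i - 1L, "m"], nu[i - 1L, "a"], spec)
    cand <- swing_foot_for_target(spec$variable, q_next, stance, s,
                                  z_B_prev = z_B[i - 1L])
    cl <- clamp_to_constraints(cand, stance, s, constraints)
    n_boundary <- n_boundary + cl$boundary_clamped
    n_width <- n_width + cl$width_clamped
    if (s == "L") { z_L[i] <- cl$z_new; z_R[i] <- stance }
    else { z_R[i] <- cl$z_new; z_L[i] <- stance }
    z_B[i] <- (z_L[i] + z_R[i]) / 2
    w[i] <- z_R[i] - z_L[i]
  }
  placed <- c(if (config$first_swing == "L") "R" else "L", sides)
  foot_placement_trial(z_L, z_R, placed, meta = list(
    model = "uni", variable = spec$variable, seed = config$seed,
    constrained = constraints$enforce,
    clamped_boundary = n_boundary, clamped_width = n_width))
}

#' Simulate a multi-objective stepping trial
#'
#' Two single-variable controllers run in parallel, each with its own
#' noise sub-stream derived from `config$seed`.  At each step each
#' objective independently proposes a swing-foot placement; the foot is
#' placed at the weighted average `(1 - rho) * z1 + rho * z2`, then
#' projected onto the feasible interval when constraints are enforced.
#' Both controllers read their next-state errors off the realized
#' geometry, so the two objectives interact only through the placed foot.
#'
#' @param mspec a [multi_objective_spec()].
#' @inheritParams simulate_uni_objective
#' @return a [foot_placement_trial()].
#' @examples
#' m <- multi_objective_spec(regulator_spec("z_B"), regulator_spec("w"), 0.93)
#' tr <- simulate_multi_objective(m, simulation_config(n_steps = 50, seed = 3))
#' @export
simulate_multi_objective <- function(mspec, config,
                                     constraints = constraint_spec()) {
  stopifnot(inherits(mspec, "multi_objective_spec"),
            inherits(config, "simulation_config"),
            inherits(constraints, "constraint_spec"))
  n <- config$n_steps
  specs <- list(mspec$spec1, mspec$spec2)
  gains <- vapply(specs, function(s)
    optimal_gain(s$sigma_m, s$gamma_over_alpha), numeric(1))
  nus <- lapply(specs, function(s)
    noise_stream(config$seed, s$variable, n - 1L))

  z_L <- numeric(n); z_R <- numeric(n)
  w0 <- .resolve_w0(config, specs)
  feet <- feet_from_state(config$z_B0, w0)
  z_L[1L] <- feet$z_L; z_R[1L] <- feet$z_R
  z_B <- numeric(n); w <- numeric(n)
  z_B[1L] <- config$z_B0; w[1L] <- w0

  sides <- rep_len(if (config$first_swing == "L") c("L", "R") else c("R", "L"),
                   n - 1L)
  n_boundary <- 0L; n_width <- 0L
  for (i in 2:n) {
    s <- sides[i - 1L]
    stance <- if (s == "L") z_R[i - 1L] else z_L[i - 1L]
    cand <- numeric(2L)
    for (j in 1:2) {
      sp <- specs[[j]]
      q_n <- .current_q(sp$variable, z_B, w, i - 1L)
      u <- -gains[j] * (q_n - sp$q_star)
      q_next <- state_update(q_n, u, nus[[j]][i - 1L, "m"],
                             nus[[j]][i - 1L, "a"], sp)
      cand[j] <- swing_foot_for_target(sp$variable, q_next, stance, s,
                                       z_B_prev = z_B[i - 1L])
    }
    mixed <- (1 - mspec$rho) * cand[1L] + mspec$rho * cand[2L]
    cl <- clamp_to_constraints(mixed, stance, s, constraints)
    n_boundary <- n_boundary + cl$boundary_clamped
    n_width <- n_width + cl$width_clamped
    if (s == "L") { z_L[i] <- cl$z_new; z_R[i] <- stance }
    else { z_R[i] <- cl$z_new; z_L[i] <- stance }
    z_B[i] <- (z_L[i] + z_R[i]) / 2
    w[i] <- z_R[i] - z_L[i]
  }
  placed <- c(if (config$first_swing == "L") "R" else "L", sides)
  foot_placement_trial(z_L, z_R, placed, meta = list(
    model = "multi",
    variables = c(mspec$spec1$variable, mspec$spec2$variable),
    rho = mspec$rho, seed = config$seed, constrained = constraints$enforce,
    clamped_boundary = n_boundary, clamped_width = n_width))
}

#' Constraint-violation percentages of a trial
#'
#' @param trial a [foot_placement_trial()].
#' @param constraints a [constraint_spec()] (limits used; `enforce`
#'   ignored).
#' @return list with `pct_boundary` (percentage of steps whose newly
#'   placed foot lies outside the lateral boundary) and `pct_width`
#'   (percentage of steps whose resulting step width falls outside the
#'   step-width limits).
#' @export
violation_rates <- function(trial, constraints = constraint_spec()) {
  stopifnot(inherits(trial, "foot_placement_trial"),
            inherits(constraints, "constraint_spec"))
  placed_z <- ifelse(trial$placed_side == "L", trial$z_L, trial$z_R)
  n <- length(placed_z)
  w <- trial$z_R - trial$z_L
  list(
    pct_boundary = 100 * sum(abs(placed_z) > constraints$z_max) / n,
    pct_width = 100 * sum(w < constraints$w_min | w > constraints$w_max) / n
  )
}

#' Additive noise level producing a target stationary output SD
#'
#' Under regulation the controlled variable follows an AR(1) map with
#' coefficient `a = 1 - g G` (neglecting multiplicative noise), whose
#' stationary SD is `sigma_a / sqrt(1 - a^2)`.  Inverting gives the
#' additive noise SD that reproduces a desired output variability, e.g.
#' one measured from human trials.
#'
#' @param target_output_sd desired stationary SD of the controlled
#'   variable (m), >= 0.
#' @param spec a [regulator_spec()] (its `sigma_a` is ignored).
#' @param refine if `TRUE`, polish the closed form with a long seeded
#'   simulation of the scalar map (accounts for multiplicative noise).
#' @param refine_steps,refine_seed length and seed of the refinement run.
#' @return calibrated `sigma_a` (m).
#' @export
calibrate_additive_noise <- function(target_output_sd, spec,
                                     refine = FALSE,
                                     refine_steps = 2e5, refine_seed = 1) {
  stopifnot(inherits(spec, "regulator_spec"))
  if (!is.finite(target_output_sd) || target_output_sd < 0)
    stop("target_output_sd must be >= 0")
  G <- optimal_gain(spec$sigma_m, spec$gamma_over_alpha)
  a <- 1 - spec$g * G
  if (abs(a) >= 1)
    stop("|1 - g*G| >= 1: the controlled variable is non-stationary, ",
         "cannot calibrate")
  sigma_a <- target_output_sd * sqrt(1 - a^2)
  if (refine && sigma_a > 0) {
    sd1 <- .scalar_map_sd(spec, sigma_a, refine_steps, refine_seed)
    sigma_a <- sigma_a * target_output_sd / sd1
  }
  sigma_a
}

# Stationary SD of the scalar regulated map at a given sigma_a.
.scalar_map_sd <- function(spec, sigma_a, n, seed) {
  G <- optimal_gain(spec$sigma_m, spec$gamma_over_alpha)
  with_seed(seed, {
    nu_m <- stats::rnorm(n); nu_a <- stats::rnorm(n)
    q <- numeric(n + 1L)
    for (i in seq_len(n)) {
      u <- -G * q[i]
      q[i + 1L] <- q[i] + spec$g * (1 + spec$sigma_m * nu_m[i]) * u +
        sigma_a * nu_a[i]
    }
    stats::sd(q[-seq_len(min(1000L, n %/% 10L))])
  })
}
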