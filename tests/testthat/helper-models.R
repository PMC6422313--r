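# Shared model configurations for the test suite.

no_constraints <- function() constraint_spec(enforce = FALSE)

baseline_multi <- function(rho = 0.93)
  multi_objective_spec(regulator_spec("z_B"), regulator_spec("w"), rho)

noiseless_spec <- function(variable, ...)
  regulator_spec(variable, sigma_a = 0, sigma_m = 0, ...)

# Mean of a per-trial statistic of a uni-objective regulator over n trials.
mean_uni_stat <- function(variable, stat_fn, n_trials = 30, seed_base = 0,
                          n_steps = 290, constraints = no_constraints()) {
  vals <- vapply(seq_len(n_trials), function(t) {
    tr <- simulate_uni_objective(
      regulator_spec(variable),
      simulation_config(n_steps = n_steps, seed = seed_base + t),
      constraints)
    stat_fn(derive_state_series(tr))
  }, numeric(1))
  mean(vals)
}
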