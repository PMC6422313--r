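test_that("optimal gain follows the closed form and its limits", {
  expect_identical(optimal_gain(0, 0), 1)       # unbiased proportional limit
  expect_identical(optimal_gain(1, 0), 0.5)
  # independent arithmetic for the baseline-like case
  expect_equal(optimal_gain(0.00257, 0.1), 1 / (1 + 0.00257^2 + 0.1))
  expect_error(optimal_gain(-0.1, 0), ">= 0")
  expect_error(optimal_gain(0, -1), ">= 0")
})

test_that("optimal gain strictly decreases in both noise and effort cost", {
  sm <- seq(0, 2, by = 0.25)
  ga <- seq(0, 2, by = 0.25)
  for (g0 in ga) {
    gains <- optimal_gain(sm, g0)
    expect_true(all(diff(gains) < 0))
    expect_true(all(gains > 0 & gains <= 1))
  }
  for (s0 in sm) {
    gains <- optimal_gain(s0, ga)
    expect_true(all(diff(gains) < 0))
  }
})

test_that("control input is proportional error feedback", {
  sp <- regulator_spec("w")
  expect_identical(control_input(sp$q_star, sp), 0)
  unb <- regulator_spec("w", sigma_m = 0, gamma_over_alpha = 0)
  expect_equal(control_input(unb$q_star + 0.05, unb), -0.05)
  sp2 <- regulator_spec("z_B", sigma_m = 0.00257, gamma_over_alpha = 0.1)
  G <- 1 / (1 + 0.00257^2 + 0.1)
  expect_equal(control_input(0.02, sp2), -G * 0.02)
})

test_that("the state update map behaves as written", {
  sp <- regulator_spec("z_B", sigma_a = 0.01)
  # noise-free: q + u
  expect_identical(state_update(0.3, -0.1, 0, 0, sp), 0.3 - 0.1)
  # pure drift: additive noise only
  expect_equal(state_update(0.3, 0, 0, 1, sp), 0.3 + 0.01)
  # unbiased controller corrects fully in one step
  unb <- regulator_spec("z_B", sigma_a = 0, sigma_m = 0,
                        gamma_over_alpha = 0)
  q1 <- state_update(0.3, control_input(0.3, unb), 0, 0, unb)
  expect_identical(q1, unb$q_star)
})

test_that("noise-free error contracts geometrically at rate 1 - G", {
  for (ga in c(0, 0.1, 0.5)) {
    sp <- regulator_spec("w", sigma_a = 0, sigma_m = 0,
                         gamma_over_alpha = ga)
    G <- optimal_gain(0, ga)
    q <- sp$q_star + 0.08
    for (n in 1:10) {
      q_next <- state_update(q, control_input(q, sp), 0, 0, sp)
      expect_lt(abs((q_next - sp$q_star) - (1 - G) * (q - sp$q_star)),
                1e-15)
      q <- q_next
    }
  }
})

test_that("the unbiased controller has zero mean error (Monte Carlo)", {
  sp <- regulator_spec("w", sigma_m = 0, gamma_over_alpha = 0,
                       sigma_a = 0.025)
  n <- 1e5
  set.seed(1234)
  nu_a <- rnorm(n)
  q0 <- sp$q_star + 0.05
  q1 <- state_update(rep(q0, n), control_input(q0, sp), 0, nu_a, sp)
  err <- q1 - sp$q_star
  sem <- sd(err) / sqrt(n)
  expect_lt(abs(mean(err)), 4 * sem)
})

test_that("swing-foot placement realizes the controller's target", {
  # step-width inversion: stance R at 0.10, target w = 0.12, swing L
  expect_equal(swing_foot_for_target("w", 0.12, 0.10, "L"), -0.02)
  # position inversion: stance L at -0.06, target z_B = 0, swing R
  expect_equal(swing_foot_for_target("z_B", 0, -0.06, "R"), 0.06)
  # heading inversion, forward-checked through derive_state_series
  z_new <- swing_foot_for_target("dz_B", 0, 0.10, "L", z_B_prev = 0.02)
  expect_equal(z_new, -0.06)
  prev <- feet_from_state(0.02, 0.10 - z_new)  # same z_B_prev, stance R
  tr <- foot_placement_trial(c(prev$z_L, z_new), c(0.10, 0.10), c("R", "L"))
  expect_equal(derive_state_series(tr)$dz_B, 0)
  expect_error(swing_foot_for_target("speed", 0, 0, "L"), "unknown variable")
  expect_error(swing_foot_for_target("w", 0.1, 0, "X"), "swing_side")
})

test_that("clamping projects onto the feasible interval and flags the binding limit", {
  cs <- constraint_spec()
  # inside all limits: unchanged
  r <- clamp_to_constraints(-0.02, 0.10, "L", cs)
  expect_identical(r, list(z_new = -0.02, boundary_clamped = FALSE,
                           width_clamped = FALSE))
  # lateral boundary binds
  r <- clamp_to_constraints(0.90, 0.80, "R", cs)
  expect_identical(r$z_new, 0.885)
  expect_true(r$boundary_clamped)
  expect_false(r$width_clamped)
  # step-width limit binds: swing L past the stance foot (crossover)
  r <- clamp_to_constraints(0.05, 0, "L", cs)
  expect_equal(r$z_new, 0.0015)
  expect_true(r$width_clamped)
  expect_false(r$boundary_clamped)
  # enforce = FALSE passes through
  r <- clamp_to_constraints(5, 0, "L", constraint_spec(enforce = FALSE))
  expect_identical(r$z_new, 5)
  # inconsistent configuration: no feasible placement
  expect_error(clamp_to_constraints(0, 0.89, "R", cs), "empty feasible")
})

test_that("noise-free width control locks step width and body position", {
  sp <- noiseless_spec("w")
  tr <- simulate_uni_objective(sp, simulation_config(n_steps = 30, seed = 1),
                               no_constraints())
  s <- derive_state_series(tr)
  expect_equal(s$w, rep(0.127, 30))
  expect_equal(s$z_B, rep(0, 30))
})

test_that("identical seeds give bit-identical trials", {
  cfg <- simulation_config(n_steps = 100, seed = 42)
  a <- simulate_uni_objective(regulator_spec("z_B"), cfg)
  b <- simulate_uni_objective(regulator_spec("z_B"), cfg)
  expect_identical(a, b)
  m <- baseline_multi()
  expect_identical(simulate_multi_objective(m, cfg),
                   simulate_multi_objective(m, cfg))
  c2 <- simulation_config(n_steps = 100, seed = 43)
  expect_false(identical(simulate_uni_objective(regulator_spec("z_B"), cfg),
                         simulate_uni_objective(regulator_spec("z_B"), c2)))
})

test_that("width-only control leaves lag-1 autocorrelation 1 - G in step width", {
  sp <- regulator_spec("w")
  G <- optimal_gain(sp$sigma_m, sp$gamma_over_alpha)
  tr <- simulate_uni_objective(sp, simulation_config(n_steps = 8000, seed = 9),
                               no_constraints())
  w <- derive_state_series(tr)$w
  expect_lt(abs(acf(w, plot = FALSE)$acf[2] - (1 - G)), 0.05)
})

test_that("a pure-width mixture reproduces the uni-objective width run", {
  cfg <- simulation_config(n_steps = 150, seed = 5)
  m <- multi_objective_spec(noiseless_spec("z_B"), regulator_spec("w"),
                            rho = 1)
  tm <- simulate_multi_objective(m, cfg, no_constraints())
  tu <- simulate_uni_objective(regulator_spec("w"), cfg, no_constraints())
  expect_identical(tm$z_L, tu$z_L)
  expect_identical(tm$z_R, tu$z_R)
})

test_that("noise-free position-width mixture converges to the joint goal point", {
  m <- multi_objective_spec(noiseless_spec("z_B"), noiseless_spec("w"),
                            rho = 0.93)
  # start far from the goal; fixed point satisfies both objectives
  cfg <- simulation_config(n_steps = 250, seed = 1, z_B0 = 0.3, w0 = 0.05)
  tr <- simulate_multi_objective(m, cfg, no_constraints())
  n <- n_steps(tr)
  expect_equal(tr$z_L[n], 0 - 0.127 / 2, tolerance = 1e-9)
  expect_equal(tr$z_R[n], 0 + 0.127 / 2, tolerance = 1e-9)
})

test_that("violation rates count placements and widths outside the limits", {
  cs <- constraint_spec()
  tr <- simulate_multi_objective(baseline_multi(),
                                 simulation_config(n_steps = 290, seed = 2),
                                 cs)
  v <- violation_rates(tr, cs)
  expect_identical(v$pct_boundary, 0)
  expect_identical(v$pct_width, 0)

  # hand-built trial: exactly one placed foot off the path, widths legal
  z_R <- rep(0.1, 290); z_R[49] <- 0.90   # step 48, an "R" placement
  z_L <- z_R - 0.127
  tr2 <- foot_placement_trial(z_L, z_R, rep_len(c("R", "L"), 290))
  v2 <- violation_rates(tr2, cs)
  expect_equal(v2$pct_width, 0)
  expect_equal(v2$pct_boundary, 100 / 290)
})

test_that("additive-noise calibration matches a long-run simulation", {
  unb <- regulator_spec("w", sigma_m = 0, gamma_over_alpha = 0)
  expect_identical(calibrate_additive_noise(0.03, unb), 0.03)
  expect_identical(calibrate_additive_noise(0, regulator_spec("w")), 0)

  sp <- regulator_spec("w", sigma_m = 0.00257, gamma_over_alpha = 0.1)
  sigma_a <- calibrate_additive_noise(0.0257, sp)
  G <- optimal_gain(sp$sigma_m, sp$gamma_over_alpha)
  expect_equal(sigma_a, 0.0257 * sqrt(1 - (1 - G)^2))
  # oracle: simulate the scalar map long enough and compare the output SD
  sp_cal <- regulator_spec("w", sigma_a = sigma_a, sigma_m = sp$sigma_m,
                           gamma_over_alpha = sp$gamma_over_alpha)
  tr <- simulate_uni_objective(sp_cal,
                               simulation_config(n_steps = 2e4, seed = 77),
                               no_constraints())
  expect_lt(abs(sd(derive_state_series(tr)$w) - 0.0257), 0.001)

  # non-stationary configuration is rejected
  over <- regulator_spec("w", g = 3, sigma_m = 0, gamma_over_alpha = 0)
  expect_error(calibrate_additive_noise(0.02, over), "non-stationary")
})
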