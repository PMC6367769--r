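test_that("reference postures carry the published joint configuration", {
  p <- reference_posture("correct")
  expect_equal(p$lkfa, 109)
  expect_equal(p$rkfa, 97)
  expect_equal(p$lefa, 14.1)
  expect_equal(p$refa, 3.7)
  expect_equal(p$trunk_incl, 23.4)
  s <- reference_posture("shallow")
  expect_equal(s$lkfa, 101)
  expect_equal(s$rkfa, 89)
  expect_equal(s$lefa, p$lefa)
  expect_error(reference_posture("upright"), "correct, shallow")
})

test_that("identical configurations generate bit-identical trials", {
  cfg <- trial_config(duration_s = 15, seed = 77)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a$kinematic, b$kinematic)
  expect_identical(a$manikin, b$manikin)
  c <- generate_trial(trial_config(duration_s = 15, seed = 78))
  expect_false(identical(a$kinematic, c$kinematic))
})

test_that("cycle-detected depth and rate match the configured values", {
  tr <- generate_trial(trial_config(duration_s = 60, depth_mm = 50,
                                    rate_cpm = 110, noise_sd_mm = 0, seed = 4))
  cyc <- detect_cycles(tr$manikin)
  expect_equal(cyc$mean_depth_mm, 50, tolerance = 0.5 / 50)
  expect_equal(cyc$rate_cpm, 110, tolerance = 1 / 110)
  # within 1% even at another depth/rate
  tr2 <- generate_trial(trial_config(duration_s = 60, depth_mm = 38,
                                     rate_cpm = 100, noise_sd_mm = 0, seed = 5))
  cyc2 <- detect_cycles(tr2$manikin)
  expect_equal(cyc2$mean_depth_mm, 38, tolerance = 0.01)
})

test_that("per-minute drift moves depth as configured", {
  tr <- generate_trial(trial_config(duration_s = 180, depth_mm = 50,
                                    drift = c(depth_mm = -4), depth_cv = 0,
                                    noise_sd_mm = 0, seed = 2))
  tab <- build_feature_table(tr$kinematic, tr$manikin, lag_s = 0)
  expect_equal(diff(tab$depth_mm), rep(-4, 2), tolerance = 0.05)
})

test_that("non-physical geometry is rejected", {
  short_arms <- c(hand = 30, forearm = 60, arm = 60, trunk = 520,
                  upper_leg = 460, lower_leg = 420)
  expect_error(
    generate_trial(trial_config(segment_lengths = short_arms, duration_s = 10)),
    "cannot reach"
  )
  expect_error(
    generate_trial(trial_config(depth_mm = 600, duration_s = 10)),
    "cannot reach"
  )
})

test_that("equicorrelation solver matches the closed form and flags impossibles", {
  beta <- default_depth_betas()
  rho <- solve_equicorrelation(beta, 0.418)
  expect_equal(rho, -0.166, tolerance = 0.01)
  # independence case: R^2 target equal to sum of squared betas
  expect_equal(solve_equicorrelation(beta, sum(beta^2)), 0)
  expect_error(solve_equicorrelation(beta, 0.9), "attainable")
  # population R^2 reproduces the target through the correlation matrix
  R <- matrix(rho, 4, 4); diag(R) <- 1
  expect_equal(drop(t(beta) %*% R %*% beta), 0.418, tolerance = 1e-12)
})

test_that("feature generator reproduces its population coefficients at large n", {
  cfg <- stats_gen_config(n_rows = 1e5, seed = 2024)
  tab <- generate_feature_table(cfg)
  fit <- standardized_ols(tab[, c("rate_cpm", "pl_mm", "lkfa", "lefa")],
                          tab$depth_mm)
  expect_equal(unname(fit$beta), unname(cfg$beta), tolerance = 0.012)
  expect_equal(fit$adj_r2, 0.418, tolerance = 0.015)
  # physical-unit scales round-trip
  expect_equal(unname(colMeans(tab[, c("rate_cpm", "pl_mm", "lkfa", "lefa")])),
               unname(cfg$pred_means), tolerance = 0.02)
})

test_that("feature generator is deterministic under a fixed seed", {
  a <- generate_feature_table(stats_gen_config(n_rows = 50, seed = 9))
  b <- generate_feature_table(stats_gen_config(n_rows = 50, seed = 9))
  expect_identical(as.data.frame(a), as.data.frame(b))
})
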