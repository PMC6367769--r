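test_that("flexion angle follows the zero-when-straight convention", {
  expect_equal(flexion_angle(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(flexion_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(flexion_angle(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_error(flexion_angle(c(0, 0, 0), c(1, 0, 0)), "zero length")
})

test_that("flexion angle is invariant to rigid rotation and positive rescaling", {
  set.seed(7)
  for (i in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    ang <- flexion_angle(u, v)
    R <- random_rotation()
    expect_equal(flexion_angle(drop(R %*% u), drop(R %*% v)), ang,
                 tolerance = 1e-9)
    expect_equal(flexion_angle(runif(1, 0.1, 9) * u, runif(1, 0.1, 9) * v),
                 ang, tolerance = 1e-9)
  }
})

test_that("trunk inclination measures elevation above the horizontal plane", {
  expect_equal(trunk_inclination(c(0, 0, 1)), 90)
  expect_equal(trunk_inclination(c(1, 0, 0)), 0)
  expect_equal(trunk_inclination(c(1, 0, 1)), 45)
  expect_equal(trunk_inclination(c(0, 0, -2)), 90) # orientation-sign free
  expect_error(trunk_inclination(c(0, 0, 0)), "zero length")
})

test_that("compression-axis deviation is the palm-to-C7 angle from vertical", {
  expect_equal(compression_axis_deviation(c(0, 0, 0), c(0, 0, 500)), 0)
  expect_equal(compression_axis_deviation(c(0, 0, 0), c(300, 0, 300)), 45)
  # tan(alpha) = 0.1763 -> alpha = 10 degrees
  expect_equal(compression_axis_deviation(c(0, 0, 0), c(0.17632698, 0, 1)), 10,
               tolerance = 1e-6)
  expect_error(compression_axis_deviation(c(1, 2, 3), c(1, 2, 3)), "coincide")
})

test_that("compression-axis deviation is invariant to rotation about vertical", {
  set.seed(11)
  for (i in 1:15) {
    p <- rnorm(3); q <- p + c(rnorm(2), runif(1, 0.5, 2))
    ang <- compression_axis_deviation(p, q)
    th <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    expect_equal(compression_axis_deviation(drop(Rz %*% p), drop(Rz %*% q)),
                 ang, tolerance = 1e-9)
  }
})

test_that("vertical force fraction is cos(alpha), strictly decreasing", {
  expect_equal(vertical_force_fraction(0), 1)
  f <- vertical_force_fraction(seq(0, 90, by = 0.5))
  expect_true(all(diff(f) < 0))
  expect_error(vertical_force_fraction(-1), "\\[0, 90\\]")
  expect_error(vertical_force_fraction(91), "\\[0, 90\\]")
})

test_that("pose extraction conserves frames and flags undefined geometry", {
  tr <- quiet_trial(duration_s = 12)
  ps <- extract_pose_series(tr$kinematic)
  expect_equal(nrow(ps), tr$meta$n_frames)
  expect_false(any(ps$flagged))
  expect_true(all(ps$alpha_dev >= 0 & ps$alpha_dev <= 90))

  # a degenerate frame (palm == c7) is flagged, not dropped
  kin <- tr$kinematic
  i_c7 <- which(kin$sensor_id == "c7th1")[1]
  i_pr <- which(kin$sensor_id == "palm_right")[1]
  kin[i_pr, c("x_mm", "y_mm", "z_mm")] <- kin[i_c7, c("x_mm", "y_mm", "z_mm")]
  ps2 <- extract_pose_series(kin)
  expect_equal(nrow(ps2), nrow(ps))
  expect_true(ps2$flagged[1])
})

test_that("pose extraction errors name the missing sensor", {
  tr <- quiet_trial(duration_s = 12)
  kin <- dplyr::filter(tr$kinematic, sensor_id != "knee_left")
  expect_error(extract_pose_series(kin), "knee_left")
})

test_that("a straight right elbow is extracted as zero flexion", {
  pose <- posture_pose(lkfa = 109, rkfa = 97, lefa = 14.1, refa = 0,
                       trunk_incl = 23.4)
  tr <- generate_trial(trial_config(pose = pose, duration_s = 12,
                                    noise_sd_mm = 0, seed = 1))
  ps <- extract_pose_series(tr$kinematic)
  expect_lt(max(abs(ps$refa)), 1e-6)
})
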