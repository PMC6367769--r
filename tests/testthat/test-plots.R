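test_that("plot builders return ggplot objects", {
  tr <- quiet_trial(duration_s = 15, noise_sd_mm = 0.5, seed = 61)
  expect_s3_class(autoplot(tr), "ggplot")
  ps <- extract_pose_series(tr$kinematic)
  expect_s3_class(autoplot(ps), "ggplot")
  set.seed(1)
  ell <- ellipse_area_95(cbind(rnorm(200), rnorm(200)))
  expect_s3_class(autoplot(ell), "ggplot")
  tab <- group_by_depth(tibble::tibble(depth_mm = c(45, 35, 44, 33),
                                       pl_mm = c(3000, 2200, 2900, 2100)))
  expect_s3_class(plot_feature_groups(tab, "pl_mm"), "ggplot")
  expect_error(plot_feature_groups(tab, "ea_mm2"), "ea_mm2")
})
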