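test_that("projection keeps the named plane's coordinates in order", {
  pts <- tibble::tibble(x_mm = c(1, 4), y_mm = c(2, 5), z_mm = c(3, 6))
  h <- project_trajectory(pts, "horizontal")
  s <- project_trajectory(pts, "sagittal")
  expect_equal(h$u_mm, c(1, 4)); expect_equal(h$v_mm, c(2, 5))
  expect_equal(s$u_mm, c(1, 4)); expect_equal(s$v_mm, c(3, 6))
  expect_equal(nrow(h), nrow(pts))
  expect_error(project_trajectory(pts, "frontal"))
})

test_that("path length sums consecutive segment lengths", {
  expect_equal(path_length(cbind(3, 4)), 0) # single point
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(path_length(square), 3)
})

test_that("path length is additive over concatenation and rigid-invariant", {
  set.seed(21)
  for (i in 1:10) {
    a <- cbind(rnorm(8), rnorm(8))
    b <- rbind(a[8, ], cbind(rnorm(5), rnorm(5))) # shares an endpoint
    expect_equal(path_length(rbind(a, b[-1, ])),
                 path_length(a) + path_length(b), tolerance = 1e-9)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- sweep(a %*% R, 2, rnorm(2), `+`)
    expect_equal(path_length(moved), path_length(a), tolerance = 1e-9)
  }
})

test_that("95% ellipse has the analytic area for isotropic normal sway", {
  set.seed(5)
  m <- cbind(rnorm(2e4), rnorm(2e4))
  ell <- ellipse_area_95(m)
  expect_equal(ell$area_mm2, pi * qchisq(0.95, 2), tolerance = 0.03 * 18.8)
  expect_true(ell$semi_axes[["a"]] >= ell$semi_axes[["b"]])
  expect_equal(ell$area_mm2,
               pi * ell$semi_axes[["a"]] * ell$semi_axes[["b"]])
})

test_that("ellipse area is rotation/translation invariant and scales as s^2", {
  set.seed(6)
  m <- cbind(rnorm(500, sd = 3), rnorm(500, sd = 1))
  a0 <- ellipse_area_95(m)$area_mm2
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(ellipse_area_95(m %*% R)$area_mm2, a0, tolerance = 1e-9)
  expect_equal(ellipse_area_95(sweep(m, 2, c(10, -4), `+`))$area_mm2, a0,
               tolerance = 1e-9)
  s <- 2.5
  expect_equal(ellipse_area_95(s * m)$area_mm2, s^2 * a0, tolerance = 1e-9)
})

test_that("chi-square ellipse covers ~95% of normal sway; quantile variant exactly", {
  set.seed(8)
  S <- matrix(c(4, 1.2, 1.2, 1), 2, 2)
  L <- chol(S)
  m <- cbind(rnorm(2e4), rnorm(2e4)) %*% L
  ell <- ellipse_area_95(m)
  expect_gt(ellipse_coverage(ell, m), 0.94)
  expect_lt(ellipse_coverage(ell, m), 0.96)
  ellq <- ellipse_area_95(m, method = "quantile")
  expect_equal(ellipse_coverage(ellq, m), 0.95, tolerance = 0.002)
})

test_that("degenerate trajectories are rejected", {
  expect_error(ellipse_area_95(cbind(1:2, 1:2)), "degenerate")
  expect_error(ellipse_area_95(cbind(1:50, 2 * (1:50))), "degenerate") # collinear
})

test_that("ellipse tidy() reports the geometry", {
  set.seed(9)
  td <- tidy(ellipse_area_95(cbind(rnorm(100), rnorm(100))))
  expect_named(td, c("center_u_mm", "center_v_mm", "semi_axis_a_mm",
                     "semi_axis_b_mm", "orientation_deg", "area_mm2",
                     "method", "n"))
  expect_equal(td$n, 100)
})
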