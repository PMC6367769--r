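test_that("OLS matches a closed-form normal-equations oracle on small inputs", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(8:12, 1)
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    y <- rnorm(n)
    fit <- standardized_ols(X, y)

    M <- cbind(1, as.matrix(X))
    b_oracle <- solve(t(M) %*% M, t(M) %*% y)
    resid <- y - M %*% b_oracle
    s2 <- sum(resid^2) / (n - 3)
    se_oracle <- sqrt(diag(s2 * solve(t(M) %*% M)))

    expect_equal(unname(fit$b), unname(drop(b_oracle)), tolerance = 1e-8)
    expect_equal(unname(fit$se_b), unname(se_oracle), tolerance = 1e-8)
    r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
    expect_equal(fit$adj_r2, 1 - (1 - r2) * (n - 1) / (n - 3), tolerance = 1e-8)
  }
})

test_that("standardization identities hold on every fit", {
  set.seed(102)
  for (i in 1:5) {
    n <- 40
    X <- data.frame(a = rnorm(n, 100, 9), b = runif(n, 0, 5), c = rexp(n))
    y <- 2 * X$a - 3 * X$b + rnorm(n)
    fit <- standardized_ols(X, y)
    sx <- vapply(X, sd, numeric(1))
    expect_equal(unname(fit$beta), unname(fit$b[-1] * sx / sd(y)),
                 tolerance = 1e-10)
    expect_equal(unname(fit$b[-1] / fit$se_b[-1]),
                 unname(fit$beta / fit$se_beta), tolerance = 1e-10)
    expect_lte(fit$adj_r2, fit$r2)
    expect_equal(unname(fit$df[["residual"]]), n - ncol(X) - 1)
  }
})

test_that("an exact linear response gives adj R2 = 1 and zero residual SE", {
  X <- data.frame(u = 1:20, v = (1:20)^2)
  y <- 3 + 2 * X$u - 0.5 * X$v
  fit <- standardized_ols(X, y)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  expect_equal(fit$se_est, 0, tolerance = 1e-8)
})

test_that("rank deficiency is reported with the collinear column", {
  X <- data.frame(a = 1:15, b = 2 * (1:15), c = rnorm(15))
  expect_error(standardized_ols(X, rnorm(15)), "collinear.*b")
})

test_that("tidy and glance expose the full coefficient table", {
  tab <- generate_feature_table(stats_gen_config(n_rows = 300, seed = 5))
  fit <- standardized_ols(tab[, c("rate_cpm", "pl_mm", "lkfa", "lefa")],
                          tab$depth_mm)
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_true(is.na(td$beta[1]))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$nobs, 300)
  expect_equal(gl$df, 4)
})

test_that("Mann-Whitney U handles separation, identity and ties", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$u_stat, 0)
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$method, "exact")
  expect_equal(same$p, 1)
  mw <- mann_whitney(c(1, 3, 5), c(2, 4))
  expect_equal(mw$u_stat, u_pairwise(c(1, 3, 5), c(2, 4)))
  expect_equal(mw$p, p_enumerate(c(1, 3, 5), c(2, 4)))
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney equals the enumeration oracle for sizes <= 7", {
  set.seed(103)
  for (i in 1:12) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    a <- sample(1:6, n1, replace = TRUE) + 0.5 * rbinom(n1, 1, 0.3)
    b <- sample(1:6, n2, replace = TRUE)
    mw <- mann_whitney(a, b)
    expect_equal(mw$method, "exact")
    expect_equal(mw$u_stat, u_pairwise(a, b))
    expect_equal(mw$p, p_enumerate(a, b))
    expect_gte(mw$u_stat, 0)
    expect_lte(mw$u_stat, n1 * n2)
  }
})

test_that("large-sample Mann-Whitney agrees with the standard implementation", {
  set.seed(104)
  a <- rnorm(30); b <- rnorm(25, 0.6)
  mw <- mann_whitney(a, b)
  expect_equal(mw$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE,
                                             exact = FALSE))
  expect_equal(unname(mw$u_stat), unname(ref$statistic))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-6)
})

test_that("group comparison detects a constructed shift and routes sensibly", {
  set.seed(105)
  tab <- tibble::tibble(
    depth_mm = c(rnorm(15, 45, 1), rnorm(15, 35, 1)),
    pl_mm = c(rexp(15, 1 / 1000) + 2600, rexp(15, 1 / 1000) + 1900)
  )
  tab <- group_by_depth(tab)
  cmp <- compare_groups(tab, "pl_mm")
  expect_equal(cmp$median_deep - cmp$median_shallow, 700, tolerance = 700 * 0.8)
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$median_deep, cmp$median_shallow)

  # identical groups: zero median difference, p near 1
  tab2 <- tibble::tibble(depth_mm = c(rep(45, 6), rep(35, 6)),
                         pl_mm = rep(c(1, 2, 3, 4, 5, 6), 2))
  cmp2 <- compare_groups(group_by_depth(tab2), "pl_mm")
  expect_equal(cmp2$median_deep, cmp2$median_shallow)
  expect_equal(cmp2$p, 1)

  # single-group tables are rejected
  tab3 <- group_by_depth(tibble::tibble(depth_mm = rep(45, 5), pl_mm = rnorm(5)))
  expect_error(compare_groups(tab3, "pl_mm"), "both groups")

  # normal data routes to the t test
  tabn <- tibble::tibble(depth_mm = c(rnorm(20, 45, 1), rnorm(20, 35, 1)),
                         lkfa = c(rnorm(20, 109, 3), rnorm(20, 101, 3)))
  cmpn <- compare_groups(group_by_depth(tabn), "lkfa")
  expect_equal(cmpn$test, "t")
  expect_true(is.na(cmpn$u_stat))
})

test_that("calibrated tables show longer deep-group path lengths", {
  tab <- generate_feature_table(stats_gen_config(n_rows = 400, seed = 6))
  tab <- group_by_depth(tab)
  cmp <- compare_groups(tab, "pl_mm")
  expect_lt(cmp$median_deep, cmp$median_shallow) # beta_PL < 0 in calibration
})
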