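#' Multiple regression of compression depth with standardized coefficients
#'
#' Fits an ordinary least-squares regression of depth on the kinematic
#' predictors and reports both raw coefficients (physical units, with
#' intercept) and standardized coefficients (on z-scored variables, no
#' intercept), with standard errors, t statistics, two-sided p values,
#' adjusted R^2, the overall F test and the residual standard error. The
#' standardization identity `beta_j = b_j * s_xj / s_y` holds exactly, as does
#' `t_j = b_j / se(b_j) = beta_j / se(beta_j)`.
#'
#' @param predictors Data frame of numeric predictors (one column each), e.g.
#'   rate, path length and flexion angles from the feature table.
#' @param depth Numeric response vector (compression depth, mm), same length.
#' @return A `cpr_regression` object; see [tidy.cpr_regression()] and
#'   [glance.cpr_regression()].
#' @examples
#' tab <- generate_feature_table(stats_gen_config(n_rows = 200, seed = 3))
#' fit <- standardized_ols(tab[, c("rate_cpm", "pl_mm", "lkfa", "lefa")],
#'                         tab$depth_mm)
#' tidy(fit)
#' @export
standardized_ols <- function(predictors, depth) {
  predictors <- as.data.frame(predictors)
  if (!all(vapply(predictors, is.numeric, logical(1))) || !is.numeric(depth)) {
    stop("predictors and depth must be numeric", call. = FALSE)
  }
  n <- length(depth)
  p <- ncol(predictors)
  if (nrow(predictors) != n) stop("predictors and depth lengths differ", call. = FALSE)
  if (n <= p + 2) stop("need n > p + 2 observations", call. = FALSE)

  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  dat <- cbind(.depth = depth, predictors)
  fit <- stats::lm(.depth ~ ., data = dat)
  # a perfect fit (zero residuals) is a legitimate degenerate case here
  sm <- suppressWarnings(summary(fit))
  b <- stats::coef(fit)
  se_b <- sm$coefficients[, "Std. Error"]
  tval <- sm$coefficients[, "t value"]
  pval <- sm$coefficients[, "Pr(>|t|)"]

  sx <- vapply(predictors, stats::sd, numeric(1))
  sy <- stats::sd(depth)
  beta <- b[-1] * sx / sy
  se_beta <- se_b[-1] * sx / sy

  fstat <- unname(sm$fstatistic)
  structure(list(
    terms = names(b)[-1],
    b = b, se_b = se_b,
    beta = beta, se_beta = se_beta,
    t = tval, p = pval,
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    f_stat = fstat[1], df = c(model = fstat[2], residual = fstat[3]),
    f_p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    se_est = sm$sigma, n = n
  ), class = "cpr_regression")
}

#' @export
print.cpr_regression <- function(x, ...) {
  cat(sprintf("standardized multiple regression (n = %d)\n", x$n))
  print(tidy(x))
  cat(sprintf("adjusted R^2 = %.3f; F(%d, %d) = %.2f, p = %.3g; residual SE = %.3f\n",
              x$adj_r2, x$df[["model"]], x$df[["residual"]], x$f_stat, x$f_p,
              x$se_est))
  invisible(x)
}

#' Tidy a standardized regression fit
#'
#' @param x A `cpr_regression` from [standardized_ols()].
#' @param ... Unused.
#' @return One row per term (intercept included): raw `estimate`/`std.error`,
#'   standardized `beta`/`se_beta` (NA for the intercept), `statistic`,
#'   `p.value`.
#' @export
#' @method tidy cpr_regression
tidy.cpr_regression <- function(x, ...) {
  tibble::tibble(
    term = names(x$b),
    estimate = unname(x$b),
    std.error = unname(x$se_b),
    beta = c(NA_real_, unname(x$beta)),
    se_beta = c(NA_real_, unname(x$se_beta)),
    statistic = unname(x$t),
    p.value = unname(x$p)
  )
}

#' One-row model summary of a standardized regression fit
#'
#' @param x A `cpr_regression`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `adj.r.squared`, `sigma` (residual SE,
#'   mm), `statistic` (overall F), `p.value`, `df`, `df.residual`, `nobs`.
#' @export
#' @method glance cpr_regression
glance.cpr_regression <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2, adj.r.squared = x$adj_r2, sigma = x$se_est,
    statistic = x$f_stat, p.value = x$f_p,
    df = unname(x$df[["model"]]), df.residual = unname(x$df[["residual"]]),
    nobs = x$n
  )
}

#' Mann-Whitney U test
#'
#' U statistic with midranks for ties. The two-sided p value comes from exact
#' enumeration of all group assignments of the pooled sample when group sizes
#' are small (either group of 8 or fewer, enumeration capped at 5e5
#' combinations), and otherwise from the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param a,b Numeric samples (nonempty).
#' @return A `cpr_mann_whitney` list: `u_stat` (for sample `a`), `p`,
#'   `method` (`"exact"` or `"normal"`), `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u <- u_statistic(pooled, seq_len(n1))
  mu <- n1 * n2 / 2

  exact_ok <- (n1 <= 8 || n2 <= 8) && choose(n1 + n2, n1) <= 5e5
  if (!(n1 > 8 && n2 > 8) && exact_ok) {
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx) u_statistic(pooled, idx))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sig == 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sig
      p <- min(1, 2 * stats::pnorm(max(0, z), lower.tail = FALSE))
    }
    method <- "normal"
  }
  structure(list(u_stat = u, p = p, method = method, n_a = n1, n_b = n2),
            class = "cpr_mann_whitney")
}

u_statistic <- function(pooled, idx_a) {
  r <- rank(pooled)
  n1 <- length(idx_a)
  sum(r[idx_a]) - n1 * (n1 + 1) / 2
}

#' @export
print.cpr_mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$u_stat, x$n_a, x$n_b, x$p, x$method))
  invisible(x)
}

#' Compare a feature between the deep and shallow groups
#'
#' Reports group medians and a two-sample test of the feature across the
#' depth groups. Normality is assessed per group with the Shapiro-Wilk test
#' (alpha = 0.05); when both groups pass, a Student's t test is used,
#' otherwise the Mann-Whitney U test. The routing can be forced with `test`.
#'
#' @param table Feature table with a `group` column (see [group_by_depth()]).
#' @param feature Column name of the feature to compare.
#' @param test `"auto"` (Shapiro-Wilk gate, default), `"t"` or
#'   `"mann-whitney"`.
#' @param alpha Significance level of the normality gate.
#' @return A `cpr_group_comparison` list: medians, group sizes, `u_stat` (NA
#'   for the t route), `statistic`, `p`, `test`.
#' @export
compare_groups <- function(table, feature, test = c("auto", "t", "mann-whitney"),
                           alpha = 0.05) {
  test <- match.arg(test)
  if (!feature %in% names(table)) {
    stop("feature column '", feature, "' not found", call. = FALSE)
  }
  if (!"group" %in% names(table)) {
    stop("table lacks a group column; run group_by_depth() first", call. = FALSE)
  }
  a <- table[[feature]][table$group == "deep"]
  b <- table[[feature]][table$group == "shallow"]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("comparison needs both groups", call. = FALSE)
  }
  if (test == "auto") {
    normal <- function(x) {
      if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value > alpha
    }
    test <- if (normal(a) && normal(b)) "t" else "mann-whitney"
  }
  if (test == "t") {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    u <- NA_real_; statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    mw <- mann_whitney(a, b)
    u <- mw$u_stat; statistic <- mw$u_stat; p <- mw$p
  }
  structure(list(feature = feature,
                 median_deep = stats::median(a), median_shallow = stats::median(b),
                 n_deep = length(a), n_shallow = length(b),
                 u_stat = u, statistic = statistic, p = p, test = test),
            class = "cpr_group_comparison")
}

#' @export
print.cpr_group_comparison <- function(x, ...) {
  cat(sprintf("%s: median deep %.2f (n=%d) vs shallow %.2f (n=%d); %s test, p = %.4g\n",
              x$feature, x$median_deep, x$n_deep, x$median_shallow, x$n_shallow,
              x$test, x$p))
  invisible(x)
}

#' @export
#' @method tidy cpr_group_comparison
tidy.cpr_group_comparison <- function(x, ...) {
  tibble::tibble(
    feature = x$feature,
    median_deep = x$median_deep, median_shallow = x$median_shallow,
    n_deep = x$n_deep, n_shallow = x$n_shallow,
    u_stat = x$u_stat, statistic = x$statistic,
    p.value = x$p, test = x$test
  )
}
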