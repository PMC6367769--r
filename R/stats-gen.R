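#' Default standardized effects of the kinematic predictors on depth
#'
#' The standardized coefficients of compression rate, C7-Th1 path length,
#' left knee flexion angle and left elbow flexion angle on compression depth
#' used to calibrate the feature-level generator.
#'
#' @return Named numeric vector of four standardized coefficients.
#' @export
default_depth_betas <- function() {
  c(rate_cpm = 0.363932, pl_mm = -0.293873, lkfa = 0.290902, lefa = -0.239073)
}

#' Equicorrelation that yields a target explained variance
#'
#' For standardized predictors with an equicorrelation matrix R(rho) and
#' standardized coefficients beta, the population explained variance is
#' t(beta) R beta = sum(beta^2) + 2 * rho * sum_{i<j} beta_i beta_j. This
#' solves that scalar equation for rho and checks that R(rho) stays positive
#' definite (rho in (-1/(p-1), 1)).
#'
#' @param beta Standardized coefficients (length >= 2).
#' @param r2_target Target population R^2, in (0, 1).
#' @return The solved equicorrelation rho.
#' @export
solve_equicorrelation <- function(beta, r2_target) {
  if (r2_target <= 0 || r2_target >= 1) {
    stop("r2_target must lie in (0, 1)", call. = FALSE)
  }
  p <- length(beta)
  ss <- sum(beta^2)
  s_cross <- (sum(beta)^2 - ss) / 2
  lo <- -1 / (p - 1)
  if (abs(s_cross) < 1e-12) {
    if (abs(r2_target - ss) < 1e-12) return(0)
    stop(sprintf("no equicorrelation attains R^2 = %.4f; only %.4f is attainable",
                 r2_target, ss), call. = FALSE)
  }
  rho <- (r2_target - ss) / (2 * s_cross)
  if (rho <= lo || rho >= 1) {
    bounds <- sort(ss + 2 * c(lo, 1) * s_cross)
    stop(sprintf(paste0("no positive-definite equicorrelation attains R^2 = %.4f; ",
                        "attainable range is (%.4f, %.4f)"),
                 r2_target, bounds[1], bounds[2]), call. = FALSE)
  }
  rho
}

#' Settings for the feature-level table generator
#'
#' Describes the statistical structure used to generate per-interval feature
#' rows directly (bypassing the kinematic simulation): four correlated
#' standardized predictors with a linear effect on depth and Gaussian residual
#' noise whose variance is set by the target explained variance.
#'
#' @param n_rows Number of interval rows to generate.
#' @param beta Standardized coefficients of (rate, path length, left knee
#'   flexion, left elbow flexion) on depth; default [default_depth_betas()].
#' @param r2_target Population fraction of depth variance explained, in
#'   (0, 1); default 0.418.
#' @param pred_rho Predictor equicorrelation. `NULL` (default) solves it from
#'   `beta` and `r2_target` via [solve_equicorrelation()], so the population
#'   standardized coefficients and R^2 both match their targets.
#' @param pred_means,pred_sds Physical-unit means and SDs of the predictors:
#'   rate (cpm), path length (mm), knee and elbow flexion (degrees). Defaults
#'   are field-realistic conventions: rate (110, 10), PL (2600, 700),
#'   LKFA (103, 7), LEFA (9, 6).
#' @param depth_mean,depth_sd Mean and SD of compression depth, mm.
#' @param seed RNG seed.
#' @return A `cpr_statsgen_config` list, with the solved `pred_rho` filled in.
#' @export
stats_gen_config <- function(n_rows,
                             beta = default_depth_betas(),
                             r2_target = 0.418,
                             pred_rho = NULL,
                             pred_means = c(rate_cpm = 110, pl_mm = 2600,
                                            lkfa = 103, lefa = 9),
                             pred_sds = c(rate_cpm = 10, pl_mm = 700,
                                          lkfa = 7, lefa = 6),
                             depth_mean = 42, depth_sd = 4,
                             seed = 1L) {
  if (n_rows < 1) stop("n_rows must be >= 1", call. = FALSE)
  if (length(beta) != 4) stop("beta must have length 4", call. = FALSE)
  if (length(pred_means) != 4 || length(pred_sds) != 4 || any(pred_sds <= 0)) {
    stop("pred_means and pred_sds must give 4 values, sds positive", call. = FALSE)
  }
  if (depth_sd <= 0) stop("depth_sd must be positive", call. = FALSE)
  if (is.null(pred_rho)) {
    pred_rho <- solve_equicorrelation(beta, r2_target)
  } else if (pred_rho <= -1 / 3 || pred_rho >= 1) {
    stop("pred_rho must lie in (-1/3, 1) for a positive-definite correlation",
         call. = FALSE)
  }
  structure(list(n_rows = as.integer(n_rows), beta = beta,
                 r2_target = r2_target, pred_rho = pred_rho,
                 pred_means = pred_means, pred_sds = pred_sds,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 seed = seed),
            class = "cpr_statsgen_config")
}

#' Generate a feature table with known regression structure
#'
#' Draws standardized predictors from a 4-variate normal with equicorrelation
#' `pred_rho`, sets standardized depth to `beta' x + eps` with
#' `eps ~ N(0, 1 - r2_target)`, then maps everything to physical units. By
#' construction the population standardized coefficients equal `beta` and the
#' population R^2 equals `beta' R beta` (= `r2_target` when `pred_rho` was
#' solved for).
#'
#' @param cfg A `cpr_statsgen_config` from [stats_gen_config()].
#' @return A tibble with columns `depth_mm`, `rate_cpm`, `pl_mm`, `lkfa`,
#'   `lefa`; attributes `pred_rho` and `config` carry the calibration.
#' @examples
#' tab <- generate_feature_table(stats_gen_config(n_rows = 500, seed = 7))
#' summary(stats::lm(depth_mm ~ ., data = tab))$adj.r.squared
#' @export
generate_feature_table <- function(cfg) {
  stopifnot(inherits(cfg, "cpr_statsgen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- length(cfg$beta)
  R <- matrix(cfg$pred_rho, p, p)
  diag(R) <- 1
  Z <- matrix(stats::rnorm(cfg$n_rows * p), cfg$n_rows, p) %*% chol(R)
  depth_z <- drop(Z %*% cfg$beta) +
    stats::rnorm(cfg$n_rows, 0, sqrt(1 - cfg$r2_target))
  X <- sweep(sweep(Z, 2, cfg$pred_sds, `*`), 2, cfg$pred_means, `+`)
  out <- tibble::tibble(
    depth_mm = cfg$depth_mean + cfg$depth_sd * depth_z,
    rate_cpm = X[, 1], pl_mm = X[, 2], lkfa = X[, 3], lefa = X[, 4]
  )
  attr(out, "pred_rho") <- cfg$pred_rho
  attr(out, "config") <- cfg
  out
}
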