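#' Project a 3-D trajectory into a named anatomical plane
#'
#' The shoulder-girdle sway of the C7-Th1 sensor is analysed the way foot
#' centre-of-pressure trajectories are in posturography: projected into a
#' reference plane of the manikin's chest. `horizontal` keeps (x, y) and
#' `sagittal` keeps (x, z); point order is preserved.
#'
#' @param positions Data frame with columns `x_mm`, `y_mm`, `z_mm` (one row
#'   per frame, in order), or a 3-column numeric matrix.
#' @param plane `"horizontal"` or `"sagittal"`.
#' @return A tibble with columns `u_mm`, `v_mm` and attribute `plane`.
#' @export
project_trajectory <- function(positions, plane = c("horizontal", "sagittal")) {
  plane <- match.arg(plane)
  if (is.matrix(positions)) {
    positions <- tibble::tibble(x_mm = positions[, 1], y_mm = positions[, 2],
                                z_mm = positions[, 3])
  }
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(positions))) {
    stop("`positions` needs columns x_mm, y_mm, z_mm", call. = FALSE)
  }
  out <- if (plane == "horizontal") {
    tibble::tibble(u_mm = positions$x_mm, v_mm = positions$y_mm)
  } else {
    tibble::tibble(u_mm = positions$x_mm, v_mm = positions$z_mm)
  }
  attr(out, "plane") <- plane
  out
}

#' Sway path length
#'
#' Total length of a projected trajectory: the sum of Euclidean distances
#' between consecutive points. A single point has path length 0. Path length
#' is invariant under rigid transforms and additive over trajectories that
#' share an endpoint.
#'
#' @param traj Two-column data frame (`u_mm`, `v_mm`) from
#'   [project_trajectory()], or any two-column numeric object.
#' @return Path length in mm.
#' @export
path_length <- function(traj) {
  m <- as_traj_matrix(traj)
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums(diff(m)^2)))
}

#' 95% prediction ellipse of a projected trajectory
#'
#' The standard posturography ellipse: centred at the sample mean, axes along
#' the eigenvectors of the sample covariance, semi-axis lengths
#' `sqrt(chi2 * lambda_i)` with `chi2 = qchisq(0.95, df = 2) = 5.991`. For
#' bivariate normal sway this ellipse contains 95% of the positions in
#' expectation, and its area is `pi * 5.991 * sqrt(lambda1 * lambda2)`.
#'
#' `method = "quantile"` replaces the chi-square scale with the empirical 95th
#' percentile of the squared Mahalanobis distances of the points, so that
#' (almost) exactly 95% of the observed points fall inside regardless of their
#' distribution.
#'
#' @param traj Two-column trajectory as for [path_length()]; at least 3
#'   non-collinear points.
#' @param method `"chi2"` (default, prediction ellipse) or `"quantile"`
#'   (empirical 95th-percentile ellipse).
#' @return An object of class `cpr_ellipse`: list with `center` (u, v, mm),
#'   `semi_axes` (a >= b, mm), `orientation_deg` (major axis vs +u, degrees),
#'   `area_mm2`, `method`, `n`.
#' @export
ellipse_area_95 <- function(traj, method = c("chi2", "quantile")) {
  method <- match.arg(method)
  m <- as_traj_matrix(traj)
  if (nrow(m) < 3) stop("degenerate trajectory: fewer than 3 points", call. = FALSE)
  ctr <- colMeans(m)
  S <- stats::cov(m)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= max(ev$values) * 1e-12 || max(ev$values) <= 0) {
    stop("degenerate trajectory: rank-deficient covariance", call. = FALSE)
  }
  scale2 <- if (method == "chi2") {
    stats::qchisq(0.95, df = 2)
  } else {
    d <- stats::mahalanobis(m, ctr, S)
    stats::quantile(d, 0.95, names = FALSE, type = 7)
  }
  a <- sqrt(scale2 * ev$values[1])
  b <- sqrt(scale2 * ev$values[2])
  orient <- deg(atan2(ev$vectors[2, 1], ev$vectors[1, 1])) %% 180
  structure(
    list(center = c(u_mm = unname(ctr[1]), v_mm = unname(ctr[2])),
         semi_axes = c(a = a, b = b),
         orientation_deg = orient,
         area_mm2 = pi * a * b,
         method = method,
         n = nrow(m)),
    class = "cpr_ellipse"
  )
}

#' Fraction of trajectory points inside an ellipse
#'
#' @param ellipse A `cpr_ellipse` from [ellipse_area_95()].
#' @param traj Two-column trajectory.
#' @return Fraction in \[0, 1\].
#' @export
ellipse_coverage <- function(ellipse, traj) {
  stopifnot(inherits(ellipse, "cpr_ellipse"))
  m <- as_traj_matrix(traj)
  th <- rad(ellipse$orientation_deg)
  V <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) # axis directions
  d <- sweep(m, 2, ellipse$center) %*% V # coordinates in the ellipse frame
  a <- ellipse$semi_axes[["a"]]; b <- ellipse$semi_axes[["b"]]
  mean((d[, 1] / a)^2 + (d[, 2] / b)^2 <= 1)
}

#' @export
print.cpr_ellipse <- function(x, ...) {
  cat("95% sway ellipse (", x$method, " scaling, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  center      (%.2f, %.2f) mm\n", x$center[1], x$center[2]))
  cat(sprintf("  semi-axes   a = %.2f mm, b = %.2f mm (orientation %.1f deg)\n",
              x$semi_axes[["a"]], x$semi_axes[["b"]], x$orientation_deg))
  cat(sprintf("  area        %.1f mm^2\n", x$area_mm2))
  invisible(x)
}

#' @export
#' @method tidy cpr_ellipse
tidy.cpr_ellipse <- function(x, ...) {
  tibble::tibble(
    center_u_mm = x$center[["u_mm"]], center_v_mm = x$center[["v_mm"]],
    semi_axis_a_mm = x$semi_axes[["a"]], semi_axis_b_mm = x$semi_axes[["b"]],
    orientation_deg = x$orientation_deg, area_mm2 = x$area_mm2,
    method = x$method, n = x$n
  )
}

#' Plot a sway trajectory with its 95% ellipse
#'
#' @param object A `cpr_ellipse`.
#' @param traj Optional trajectory to draw behind the ellipse.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot cpr_ellipse
autoplot.cpr_ellipse <- function(object, traj = NULL, ...) {
  th <- seq(0, 2 * pi, length.out = 361)
  rot <- rad(object$orientation_deg)
  a <- object$semi_axes[["a"]]; b <- object$semi_axes[["b"]]
  ring <- tibble::tibble(
    u_mm = object$center[["u_mm"]] + a * cos(th) * cos(rot) - b * sin(th) * sin(rot),
    v_mm = object$center[["v_mm"]] + a * cos(th) * sin(rot) + b * sin(th) * cos(rot)
  )
  p <- ggplot2::ggplot(ring, ggplot2::aes(x = .data$u_mm, y = .data$v_mm))
  if (!is.null(traj)) {
    m <- as_traj_matrix(traj)
    pts <- tibble::tibble(u_mm = m[, 1], v_mm = m[, 2])
    p <- p + ggplot2::geom_path(data = pts, alpha = 0.35, colour = "grey40")
  }
  p +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)",
                  title = sprintf("95%% sway ellipse, area %.0f mm²", object$area_mm2))
}

as_traj_matrix <- function(traj) {
  if (is.matrix(traj)) {
    m <- traj
  } else if (is.data.frame(traj)) {
    cols <- intersect(c("u_mm", "v_mm"), names(traj))
    m <- if (length(cols) == 2) as.matrix(traj[, cols]) else as.matrix(traj[, 1:2])
  } else {
    stop("trajectory must be a 2-column matrix or data frame", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (ncol(m) != 2 || nrow(m) < 1 || !all(is.finite(m))) {
    stop("trajectory needs >= 1 row of finite (u, v) coordinates", call. = FALSE)
  }
  m
}
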