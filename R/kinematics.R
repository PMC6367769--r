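#' Flexion angle between adjacent limb segments
#'
#' Computes the flexion angle at a joint from the axes of its two adjacent
#' segments: the proximal axis points from the proximal landmark towards the
#' joint, the distal axis from the joint towards the distal landmark. With
#' this convention a fully extended (straight) limb has a flexion angle of 0
#' degrees and the angle grows towards 180 degrees as the joint folds.
#'
#' @param proximal_dir Numeric 3-vector, direction of the proximal segment
#'   (proximal landmark to joint). Need not be normalized.
#' @param distal_dir Numeric 3-vector, direction of the distal segment (joint
#'   to distal landmark). Need not be normalized.
#' @return Flexion angle in degrees, in \[0, 180\].
#' @examples
#' flexion_angle(c(1, 0, 0), c(1, 0, 0)) # straight limb: 0
#' flexion_angle(c(1, 0, 0), c(0, 1, 0)) # right angle: 90
#' @export
flexion_angle <- function(proximal_dir, distal_dir) {
  u <- check_vec3(proximal_dir, "proximal_dir")
  v <- check_vec3(distal_dir, "distal_dir")
  angle_between_deg(u, v)
}

#' Trunk inclination above the horizontal plane
#'
#' Angle between the trunk longitudinal axis (hips towards C7-Th1) and the
#' horizontal (x-y) plane. A vertical trunk scores 90 degrees, a horizontal
#' one 0.
#'
#' @param trunk_axis Numeric 3-vector along the trunk, any orientation sign.
#' @return Inclination in degrees, in \[0, 90\].
#' @export
trunk_inclination <- function(trunk_axis) {
  v <- check_vec3(trunk_axis, "trunk_axis")
  v <- v / sqrt(sum(v^2))
  deg(asin(min(1, abs(v[3]))))
}

#' Compression-axis deviation from the vertical
#'
#' The direction of the chest-compression force is taken as the line from the
#' palm sensor (on the manikin chest) to the C7-Th1 sensor at the base of the
#' rescuer's neck. This returns the angle alpha between that line and the
#' vertical axis; the vertical component of a compression force F applied
#' along the line is F * cos(alpha).
#'
#' @param palm_pos Numeric 3-point, palm-centre sensor position.
#' @param c7_pos Numeric 3-point, C7-Th1 sensor position.
#' @return Deviation angle in degrees, in \[0, 90\].
#' @seealso [vertical_force_fraction()]
#' @export
compression_axis_deviation <- function(palm_pos, c7_pos) {
  p <- check_point3(palm_pos, "palm_pos")
  q <- check_point3(c7_pos, "c7_pos")
  d <- q - p
  if (sum(d^2) == 0) {
    stop("palm_pos and c7_pos coincide; compression axis undefined", call. = FALSE)
  }
  d <- d / sqrt(sum(d^2))
  deg(acos(min(1, abs(d[3]))))
}

#' Vertical fraction of a compression force applied at a deviation angle
#'
#' A compression force F applied along an axis deviating by `alpha` degrees
#' from the vertical delivers only F * cos(alpha) perpendicular to the
#' sternum. At a 10-degree deviation the vertical force is still about 98% of
#' its maximum, and up to 25 degrees the loss stays near 10%.
#'
#' @param alpha Deviation angle(s) from vertical, degrees, in \[0, 90\].
#' @return cos(alpha), the unitless fraction of F delivered vertically.
#' @examples
#' vertical_force_fraction(c(0, 5, 10, 15, 20, 25))
#' @export
vertical_force_fraction <- function(alpha) {
  if (!is.numeric(alpha) || anyNA(alpha)) {
    stop("`alpha` must be numeric and non-missing", call. = FALSE)
  }
  if (any(alpha < 0 | alpha > 90)) {
    stop("`alpha` must lie in [0, 90] degrees", call. = FALSE)
  }
  cos(rad(alpha))
}

#' Per-frame pose angles from a kinematic sensor stream
#'
#' Reconstructs, frame by frame, the six angular features from landmark
#' sensor positions: left/right knee flexion (`lkfa`, `rkfa`), left/right
#' elbow flexion (`lefa`, `refa`), trunk inclination above the horizontal
#' (`trunk_incl`) and the compression-axis deviation from vertical
#' (`alpha_dev`, palm-to-C7-Th1 line). Segment axes are built from pairs of
#' landmark positions; all angles come from [flexion_angle()],
#' [trunk_inclination()] and [compression_axis_deviation()].
#'
#' Frames whose geometry is undefined (coincident landmarks) are kept and
#' flagged in the `flagged` column rather than dropped, so the output always
#' has one row per input frame.
#'
#' @param stream Kinematic stream: a data frame with columns `time_s`,
#'   `sensor_id`, `x_mm`, `y_mm`, `z_mm` (long form, one row per sensor per
#'   frame), as produced by [generate_trial()] or [read_kinematic_stream()].
#' @param sensor_map Named character vector mapping the anatomical roles used
#'   here to `sensor_id` values in the stream. See [default_sensor_map()] for
#'   the roles required and the default ids.
#' @return A tibble (pose series) with columns `time_s`, `lkfa`, `rkfa`,
#'   `lefa`, `refa`, `trunk_incl`, `alpha_dev`, `flagged`.
#' @export
extract_pose_series <- function(stream, sensor_map = default_sensor_map()) {
  stream <- validate_kinematic_stream(stream)
  roles <- names(default_sensor_map())
  missing_roles <- setdiff(roles, names(sensor_map))
  if (length(missing_roles) > 0) {
    stop("sensor_map lacks roles: ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  }
  present <- unique(stream$sensor_id)
  missing_sensors <- setdiff(unname(sensor_map[roles]), present)
  if (length(missing_sensors) > 0) {
    stop("stream is missing sensors: ", paste(missing_sensors, collapse = ", "),
         call. = FALSE)
  }

  # wide per-frame matrices of landmark coordinates, one per role
  pos <- lapply(roles, function(role) {
    sub <- stream[stream$sensor_id == sensor_map[[role]],
                  c("time_s", "x_mm", "y_mm", "z_mm")]
    sub <- sub[order(sub$time_s), ]
    sub
  })
  names(pos) <- roles
  nt <- vapply(pos, nrow, integer(1))
  if (length(unique(nt)) != 1) {
    stop("sensors have differing frame counts; stream is not frame-aligned",
         call. = FALSE)
  }
  time_s <- pos[[1]]$time_s
  xyz <- function(role) as.matrix(pos[[role]][, c("x_mm", "y_mm", "z_mm")])

  hip_l <- xyz("hip_left");      hip_r <- xyz("hip_right")
  knee_l <- xyz("knee_left");    knee_r <- xyz("knee_right")
  ank_l <- xyz("ankle_left");    ank_r <- xyz("ankle_right")
  sho_l <- xyz("shoulder_left"); sho_r <- xyz("shoulder_right")
  elb_l <- xyz("elbow_left");    elb_r <- xyz("elbow_right")
  pal_l <- xyz("palm_left");     pal_r <- xyz("palm_right")
  c7 <- xyz("c7th1")

  hip_mid <- (hip_l + hip_r) / 2
  trunk <- c7 - hip_mid
  axis_pc <- c7 - pal_r

  lkfa <- rows_angle_deg(knee_l - hip_l, ank_l - knee_l)
  rkfa <- rows_angle_deg(knee_r - hip_r, ank_r - knee_r)
  lefa <- rows_angle_deg(elb_l - sho_l, pal_l - elb_l)
  refa <- rows_angle_deg(elb_r - sho_r, pal_r - elb_r)

  trunk_n <- sqrt(rowSums(trunk^2))
  trunk_incl <- deg(asin(pmin(1, abs(trunk[, 3]) / pmax(trunk_n, .Machine$double.eps))))
  trunk_incl[trunk_n == 0] <- NA_real_

  pc_n <- sqrt(rowSums(axis_pc^2))
  alpha_dev <- deg(acos(pmin(1, abs(axis_pc[, 3]) / pmax(pc_n, .Machine$double.eps))))
  alpha_dev[pc_n == 0] <- NA_real_

  out <- tibble::tibble(
    time_s = time_s,
    lkfa = lkfa, rkfa = rkfa, lefa = lefa, refa = refa,
    trunk_incl = trunk_incl, alpha_dev = alpha_dev
  )
  out$flagged <- !stats::complete.cases(out[, -1])
  class(out) <- c("cpr_pose_series", class(out))
  out
}

#' Landmark roles and default sensor ids
#'
#' The pose extractor works from anatomical landmark positions (joint
#' centres), the quantities an inertial motion-capture export provides once
#' its biomechanical model has been solved. This returns the mapping from the
#' thirteen roles the reduced nine-segment chain needs to the sensor ids the
#' simulator emits; supply your own mapping to [extract_pose_series()] when
#' stream ids differ.
#'
#' @return Named character vector: role -> sensor_id.
#' @export
default_sensor_map <- function() {
  ids <- c("c7th1", "palm_left", "palm_right",
           "shoulder_left", "shoulder_right",
           "elbow_left", "elbow_right",
           "hip_left", "hip_right",
           "knee_left", "knee_right",
           "ankle_left", "ankle_right")
  stats::setNames(ids, ids)
}

# --- internal geometry helpers -------------------------------------------

rad <- function(x) x * pi / 180
deg <- function(x) x * 180 / pi

check_vec3 <- function(v, name) {
  if (!is.numeric(v) || length(v) != 3 || anyNA(v)) {
    stop("`", name, "` must be a numeric 3-vector", call. = FALSE)
  }
  if (sum(v^2) == 0) stop("`", name, "` has zero length", call. = FALSE)
  v
}

check_point3 <- function(v, name) {
  if (!is.numeric(v) || length(v) != 3 || anyNA(v)) {
    stop("`", name, "` must be a numeric 3-point", call. = FALSE)
  }
  v
}

angle_between_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  deg(acos(max(-1, min(1, cu))))
}

# row-wise angle between two matrices of 3-vectors; NA for zero rows
rows_angle_deg <- function(A, B) {
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  cu <- rowSums(A * B) / pmax(na * nb, .Machine$double.eps)
  out <- deg(acos(pmax(-1, pmin(1, cu))))
  out[na == 0 | nb == 0] <- NA_real_
  out
}
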