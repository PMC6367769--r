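#' Posture of a kneeling rescuer
#'
#' Bundles the joint configuration of the reduced nine-segment chain (hands,
#' forearms, upper arms, trunk, upper legs — with the lower legs as ground
#' contacts) used to pose the simulated rescuer. Flexion angles follow the
#' 0-degrees-straight convention; trunk inclination is measured above the
#' horizontal plane.
#'
#' @param lkfa,rkfa Left/right knee flexion angles, degrees in \[0, 180\].
#' @param lefa,refa Left/right elbow flexion angles, degrees in \[0, 180\].
#' @param trunk_incl Trunk inclination above horizontal, degrees in \[0, 90\].
#' @param hip_height Vertical hip height above the floor, mm. When `NULL`
#'   (default) it is derived from the knee angles and the thigh length
#'   (`thigh_mm`), which is what the kinematic chain enforces anyway.
#' @param thigh_mm Upper-leg length used to derive `hip_height`, mm.
#' @return A `cpr_posture` list.
#' @export
posture_pose <- function(lkfa, rkfa, lefa, refa, trunk_incl,
                         hip_height = NULL, thigh_mm = 460) {
  ang <- c(lkfa = lkfa, rkfa = rkfa, lefa = lefa, refa = refa)
  if (any(ang < 0 | ang > 180)) {
    stop("flexion angles must lie in [0, 180] degrees", call. = FALSE)
  }
  if (trunk_incl < 0 || trunk_incl > 90) {
    stop("trunk_incl must lie in [0, 90] degrees", call. = FALSE)
  }
  if (is.null(hip_height)) {
    hip_height <- thigh_mm * mean(sin(rad(c(lkfa, rkfa))))
  }
  if (!is.finite(hip_height) || hip_height <= 0) {
    stop("hip_height must be positive (knees cannot be fully extended while kneeling)",
         call. = FALSE)
  }
  structure(list(lkfa = lkfa, rkfa = rkfa, lefa = lefa, refa = refa,
                 trunk_incl = trunk_incl, hip_height = hip_height),
            class = "cpr_posture")
}

#' @export
print.cpr_posture <- function(x, ...) {
  cat("rescuer posture\n")
  cat(sprintf("  knee flexion   L %.1f / R %.1f deg\n", x$lkfa, x$rkfa))
  cat(sprintf("  elbow flexion  L %.1f / R %.1f deg\n", x$lefa, x$refa))
  cat(sprintf("  trunk incl.    %.1f deg above horizontal\n", x$trunk_incl))
  cat(sprintf("  hip height     %.0f mm\n", x$hip_height))
  invisible(x)
}

#' Reference postures for chest compression
#'
#' `"correct"` is the posture observed in rescuers who achieved adequate
#' compression depth: knee flexion 109 (left) / 97 (right) degrees, elbow
#' flexion 14.1 (left) / 3.7 (right) degrees, trunk inclined 23.4 degrees
#' above horizontal. `"shallow"` is the same posture with both knees extended
#' by 8 degrees (knee flexion reduced), the direction associated with
#' shallower compressions.
#'
#' @param preset `"correct"` or `"shallow"`.
#' @return A `cpr_posture` (see [posture_pose()]).
#' @examples
#' reference_posture("correct")
#' @export
reference_posture <- function(preset = c("correct", "shallow")) {
  if (length(preset) == 1 && !preset %in% c("correct", "shallow")) {
    stop("unknown posture preset '", preset,
         "'; valid presets: correct, shallow", call. = FALSE)
  }
  preset <- match.arg(preset)
  base <- posture_pose(lkfa = 109, rkfa = 97, lefa = 14.1, refa = 3.7,
                       trunk_incl = 23.4)
  if (preset == "correct") return(base)
  posture_pose(lkfa = base$lkfa - 8, rkfa = base$rkfa - 8,
               lefa = base$lefa, refa = base$refa,
               trunk_incl = base$trunk_incl)
}

#' Simulation settings for one compression trial
#'
#' All knobs of the forward-kinematics simulator. Defaults describe a 10-min
#' continuous-compression trial at guideline rate and depth on a manikin with
#' a compression resistance of 9.0 N/cm^2 (recorded as metadata).
#'
#' @param pose A `cpr_posture`, e.g. [reference_posture()].
#' @param segment_lengths Named numeric, mm: `hand`, `forearm`, `arm` (upper
#'   arm), `trunk`, `upper_leg`, `lower_leg`.
#' @param rate_cpm Compression rate, compressions per minute (> 0).
#' @param depth_mm Nominal compression depth (palm vertical excursion), mm.
#' @param duration_s Trial length, s (> 0).
#' @param sample_hz Kinematic sampling rate, Hz (>= 20).
#' @param noise_sd_mm SD of i.i.d. Gaussian sensor position noise, mm.
#' @param sway_amp_mm Fore-aft semi-amplitude of the elliptical C7-Th1 sway,
#'   mm (lateral semi-amplitude is half of this).
#' @param depth_cv Cycle-to-cycle coefficient of variation of the compression
#'   depth. Real rescuers never compress identically twice; the resulting
#'   smooth random envelope (shared by the palm trajectory and the manikin
#'   log, which observe the same motion) is also what makes the two streams
#'   synchronizable — a perfectly periodic signal has no unique lag.
#' @param drift Named numeric vector of linear per-minute changes emulating
#'   fatigue; allowed names: `depth_mm`, `lkfa`, `rkfa`, `lefa`, `refa`,
#'   `trunk_incl`. Default: no drift.
#' @param clock_offset_s Offset added to the manikin stream's clock, s.
#' @param seed RNG seed for the position noise.
#' @param hip_half_width,shoulder_half_width Body half-widths, mm.
#' @param arm_forward_mm Horizontal (fore-aft) offset of the palm target ahead
#'   of the shoulders, mm; sets the rest deviation of the compression axis.
#' @return A `cpr_trial_config` list.
#' @export
trial_config <- function(pose = reference_posture("correct"),
                         segment_lengths = c(hand = 75, forearm = 250,
                                             arm = 300, trunk = 520,
                                             upper_leg = 460, lower_leg = 420),
                         rate_cpm = 110,
                         depth_mm = 50,
                         duration_s = 600,
                         sample_hz = 60,
                         noise_sd_mm = 1,
                         sway_amp_mm = 10,
                         depth_cv = 0.05,
                         drift = c(depth_mm = 0),
                         clock_offset_s = 0,
                         seed = 1L,
                         hip_half_width = 100,
                         shoulder_half_width = 180,
                         arm_forward_mm = 60) {
  stopifnot(inherits(pose, "cpr_posture"))
  need <- c("hand", "forearm", "arm", "trunk", "upper_leg", "lower_leg")
  if (!all(need %in% names(segment_lengths)) || any(segment_lengths <= 0)) {
    stop("segment_lengths must name positive lengths for: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (rate_cpm <= 0) stop("rate_cpm must be > 0", call. = FALSE)
  if (depth_mm < 0) stop("depth_mm must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (sample_hz < 20) stop("sample_hz must be >= 20", call. = FALSE)
  ok_drift <- c("depth_mm", "lkfa", "rkfa", "lefa", "refa", "trunk_incl")
  if (length(drift) > 0 && !all(names(drift) %in% ok_drift)) {
    stop("drift names must be among: ", paste(ok_drift, collapse = ", "),
         call. = FALSE)
  }
  if (depth_cv < 0) stop("depth_cv must be >= 0", call. = FALSE)
  structure(list(pose = pose, segment_lengths = segment_lengths,
                 rate_cpm = rate_cpm, depth_mm = depth_mm,
                 duration_s = duration_s, sample_hz = sample_hz,
                 noise_sd_mm = noise_sd_mm, sway_amp_mm = sway_amp_mm,
                 depth_cv = depth_cv, drift = drift, clock_offset_s = clock_offset_s, seed = seed,
                 hip_half_width = hip_half_width,
                 shoulder_half_width = shoulder_half_width,
                 arm_forward_mm = arm_forward_mm,
                 manikin_resistance_n_cm2 = 9.0),
            class = "cpr_trial_config")
}

#' Simulate a chest-compression trial
#'
#' Poses the reduced nine-segment chain at the configured posture, frame by
#' frame, in a manikin-centred frame (x fore-aft along the manikin's
#' longitudinal axis, y lateral, z vertical), and superimposes: a sinusoidal
#' compression stroke at `rate_cpm` whose palm vertical excursion equals
#' `depth_mm`, applied as a rigid vertical oscillation of the whole sensor
#' cloud (the rescuer rides the recoiling chest, so the configured joint
#' angles are carried through the cycle); an elliptical fore-aft/lateral sway
#' of the C7-Th1 sensor of semi-amplitude `sway_amp_mm` (lateral half that),
#' phase-locked to the compression cycle; linear per-minute drift of depth
#' and/or pose angles; and i.i.d. Gaussian position noise.
#'
#' The manikin stream is the palm vertical excursion clipped at zero, with
#' `clock_offset_s` added to its time stamps (the two devices do not share a
#' clock). Identical configurations (including `seed`) give bit-identical
#' output.
#'
#' @param cfg A `cpr_trial_config` from [trial_config()].
#' @return A `cpr_trial` list with elements `kinematic` (tibble `time_s`,
#'   `sensor_id`, `x_mm`, `y_mm`, `z_mm`), `manikin` (tibble `time_s`,
#'   `depth_mm`), and `meta` (config echo, palm rest height, derived hip
#'   height, manikin resistance).
#' @export
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "cpr_trial_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t <- seq(0, cfg$duration_s, by = 1 / cfg$sample_hz)
  n <- length(t)
  min_t <- t / 60

  dr <- function(nm) if (nm %in% names(cfg$drift)) cfg$drift[[nm]] else 0
  ang <- list(
    lkfa = cfg$pose$lkfa + dr("lkfa") * min_t,
    rkfa = cfg$pose$rkfa + dr("rkfa") * min_t,
    lefa = cfg$pose$lefa + dr("lefa") * min_t,
    refa = cfg$pose$refa + dr("refa") * min_t,
    trunk_incl = cfg$pose$trunk_incl + dr("trunk_incl") * min_t
  )
  if (any(unlist(ang[1:4]) < 0 | unlist(ang[1:4]) > 180) ||
      any(ang$trunk_incl < 0 | ang$trunk_incl > 90)) {
    stop("drift pushes a pose angle outside its physical range", call. = FALSE)
  }

  lm <- pose_landmarks(ang, cfg$segment_lengths, cfg$hip_half_width,
                       cfg$shoulder_half_width, cfg$arm_forward_mm, n)

  # compression stroke: depth waveform, one full excursion per cycle,
  # with a smooth cycle-to-cycle depth envelope shared by both streams
  f <- cfg$rate_cpm / 60
  depth_nominal <- pmax(0, cfg$depth_mm + dr("depth_mm") * min_t)

  palm_rest_z <- min(lm$palm_right[, 3], lm$palm_left[, 3])
  if (palm_rest_z <= 0 || palm_rest_z - max(depth_nominal) < 0) {
    stop("non-physical geometry: segment chain cannot reach floor and chest ",
         "simultaneously (palm rest height ", round(palm_rest_z, 1),
         " mm vs compression depth ", round(max(depth_nominal), 1), " mm)",
         call. = FALSE)
  }

  depth_t <- depth_nominal
  if (cfg$depth_cv > 0) {
    n_cycles <- ceiling(cfg$duration_s * f) + 2
    cyc_mid <- (seq_len(n_cycles) - 0.5) / f
    env_knots <- 1 + cfg$depth_cv * stats::rnorm(n_cycles)
    env <- stats::approx(cyc_mid, env_knots, xout = t, rule = 2)$y
    # floor contact caps a rare over-deep stroke at the palm rest height
    depth_t <- pmin(pmax(0, depth_t * env), palm_rest_z)
  }
  stroke <- depth_t * (1 - cos(2 * pi * f * t)) / 2

  for (nm in names(lm)) lm[[nm]][, 3] <- lm[[nm]][, 3] - stroke

  # elliptical shoulder-girdle sway, phase-locked to the compression cycle
  lm$c7th1[, 1] <- lm$c7th1[, 1] + cfg$sway_amp_mm * sin(2 * pi * f * t)
  lm$c7th1[, 2] <- lm$c7th1[, 2] + (cfg$sway_amp_mm / 2) * cos(2 * pi * f * t)

  sensors <- names(lm)
  kin <- tibble::tibble(
    time_s = rep(t, times = length(sensors)),
    sensor_id = rep(sensors, each = n),
    x_mm = unlist(lapply(lm, function(m) m[, 1]), use.names = FALSE),
    y_mm = unlist(lapply(lm, function(m) m[, 2]), use.names = FALSE),
    z_mm = unlist(lapply(lm, function(m) m[, 3]), use.names = FALSE)
  )
  if (cfg$noise_sd_mm > 0) {
    kin$x_mm <- kin$x_mm + stats::rnorm(nrow(kin), 0, cfg$noise_sd_mm)
    kin$y_mm <- kin$y_mm + stats::rnorm(nrow(kin), 0, cfg$noise_sd_mm)
    kin$z_mm <- kin$z_mm + stats::rnorm(nrow(kin), 0, cfg$noise_sd_mm)
  }
  kin <- dplyr::arrange(kin, .data$time_s, .data$sensor_id)

  man <- tibble::tibble(time_s = t + cfg$clock_offset_s,
                        depth_mm = pmax(0, stroke))

  structure(list(
    kinematic = kin,
    manikin = man,
    meta = list(config = cfg,
                palm_rest_z_mm = palm_rest_z,
                hip_height_mm = cfg$pose$hip_height,
                manikin_resistance_n_cm2 = cfg$manikin_resistance_n_cm2,
                n_frames = n)
  ), class = "cpr_trial")
}

#' @export
print.cpr_trial <- function(x, ...) {
  cfg <- x$meta$config
  cat("simulated chest-compression trial\n")
  cat(sprintf("  %d frames at %g Hz over %g s; %d sensors\n",
              x$meta$n_frames, cfg$sample_hz, cfg$duration_s,
              length(unique(x$kinematic$sensor_id))))
  cat(sprintf("  rate %g cpm, depth %g mm, noise sd %g mm, clock offset %g s\n",
              cfg$rate_cpm, cfg$depth_mm, cfg$noise_sd_mm, cfg$clock_offset_s))
  invisible(x)
}

#' Plot the simulated manikin depth and palm height
#'
#' @param object A `cpr_trial`.
#' @param window_s Time window to show, s (default first 10 s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot cpr_trial
autoplot.cpr_trial <- function(object, window_s = 10, ...) {
  man <- dplyr::filter(object$manikin, .data$time_s <= min(.data$time_s) + window_s)
  ggplot2::ggplot(man, ggplot2::aes(x = .data$time_s, y = .data$depth_mm)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::labs(x = "time (s)", y = "compression depth (mm)",
                  title = "manikin depth signal")
}

# --- forward kinematics ----------------------------------------------------

# Pose the landmark chain for n frames. `ang` holds per-frame angle vectors.
# Returns a named list of n x 3 coordinate matrices (mm).
pose_landmarks <- function(ang, seg, hip_half_width, shoulder_half_width,
                           arm_forward_mm, n) {
  rep3 <- function(x, y, z) cbind(rep(x, length.out = n),
                                  rep(y, length.out = n),
                                  rep(z, length.out = n))

  knee_l <- rep3(0,  hip_half_width, 0)
  knee_r <- rep3(0, -hip_half_width, 0)
  # shanks flat on the floor, pointing backwards (ground contacts)
  ankle_l <- knee_l + rep3(-seg[["lower_leg"]], 0, 0)
  ankle_r <- knee_r + rep3(-seg[["lower_leg"]], 0, 0)

  hip_l <- knee_l + seg[["upper_leg"]] * cbind(cos(rad(ang$lkfa)), 0, sin(rad(ang$lkfa)))
  hip_r <- knee_r + seg[["upper_leg"]] * cbind(cos(rad(ang$rkfa)), 0, sin(rad(ang$rkfa)))
  if (any(hip_l[, 3] <= 0) || any(hip_r[, 3] <= 0)) {
    stop("non-physical geometry: hips at or below the floor", call. = FALSE)
  }
  hip_mid <- (hip_l + hip_r) / 2

  tau <- rad(ang$trunk_incl)
  c7 <- hip_mid + seg[["trunk"]] * cbind(cos(tau), 0, sin(tau))
  sho_l <- c7 + rep3(0,  shoulder_half_width, 0)
  sho_r <- c7 + rep3(0, -shoulder_half_width, 0)

  arm_len <- seg[["arm"]]
  fore_len <- seg[["forearm"]] + seg[["hand"]] # elbow to palm centre

  arm_chain <- function(shoulder, efa_deg) {
    half <- rad(efa_deg) / 2
    reach <- (arm_len + fore_len) * cos(half)
    dy <- -shoulder[, 2] # palms meet at the manikin midline
    inside <- reach^2 - arm_forward_mm^2 - dy^2
    if (any(inside <= 0)) {
      stop("non-physical geometry: segment chain cannot reach floor and chest ",
           "simultaneously (arms too short for the shoulder width)",
           call. = FALSE)
    }
    a <- cbind(arm_forward_mm, dy, -sqrt(inside)) / reach # unit, towards chest
    # bend axis: horizontal, perpendicular to the straight-arm direction
    b <- cbind(a[, 2], -a[, 1], 0)
    b <- b / sqrt(rowSums(b^2))
    bxa <- rows_cross(b, a)
    u_dir <- a * cos(half) - bxa * sin(half) # shoulder -> elbow
    f_dir <- a * cos(half) + bxa * sin(half) # elbow -> palm
    elbow <- shoulder + arm_len * u_dir
    palm <- elbow + fore_len * f_dir
    list(elbow = elbow, palm = palm)
  }

  left <- arm_chain(sho_l, ang$lefa)
  right <- arm_chain(sho_r, ang$refa)

  list(c7th1 = c7,
       palm_left = left$palm, palm_right = right$palm,
       shoulder_left = sho_l, shoulder_right = sho_r,
       elbow_left = left$elbow, elbow_right = right$elbow,
       hip_left = hip_l, hip_right = hip_r,
       knee_left = knee_l, knee_right = knee_r,
       ankle_left = ankle_l, ankle_right = ankle_r)
}

rows_cross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}
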