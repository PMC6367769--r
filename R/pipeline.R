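#' Estimate the clock offset between the kinematic and manikin streams
#'
#' Both devices observe the same physical compression cycle: the manikin logs
#' the chest depth while the palm sensor rides the rescuer's hand. The lag
#' maximizing the normalized cross-correlation between the manikin depth and
#' the negated vertical palm excursion therefore aligns the two clocks. The
#' search runs over a grid of lags at the kinematic sample period.
#'
#' @param kin Kinematic stream (long-form tibble, see [generate_trial()]).
#' @param man Manikin stream (tibble `time_s`, `depth_mm`).
#' @param max_lag_s Half-width of the lag search window, s.
#' @param palm_sensor Sensor id of the palm riding the chest.
#' @return The estimated lag in seconds: subtract it from the manikin time
#'   stamps to express both streams on the kinematic clock. The peak
#'   correlation is attached as attribute `correlation`.
#' @export
synchronize <- function(kin, man, max_lag_s = 5, palm_sensor = "palm_right") {
  kin <- validate_kinematic_stream(kin)
  man <- validate_manikin_stream(man)
  palm <- kin[kin$sensor_id == palm_sensor, c("time_s", "z_mm")]
  if (nrow(palm) == 0) {
    stop("stream is missing sensors: ", palm_sensor, call. = FALSE)
  }
  palm <- palm[order(palm$time_s), ]
  if (diff(range(palm$time_s)) < 10 || diff(range(man$time_s)) < 10) {
    stop("streams must each cover at least 10 s", call. = FALSE)
  }
  dt <- stats::median(diff(palm$time_s))
  lags <- seq(-max_lag_s, max_lag_s, by = dt)
  x <- -(palm$z_mm - mean(palm$z_mm)) # negated palm excursion ~ depth
  cors <- vapply(lags, function(lag) {
    d <- stats::approx(man$time_s - lag, man$depth_mm, xout = palm$time_s)$y
    ok <- !is.na(d)
    if (sum(ok) < 20) return(NA_real_)
    suppressWarnings(stats::cor(x[ok], d[ok]))
  }, numeric(1))
  if (all(is.na(cors)) || max(cors, na.rm = TRUE) < 0.5) {
    stop("streams do not co-vary; cannot synchronize", call. = FALSE)
  }
  lag <- lags[which.max(cors)]
  attr(lag, "correlation") <- max(cors, na.rm = TRUE)
  lag
}

#' Detect compression cycles in a manikin depth signal
#'
#' Finds local maxima of the depth signal with at least `min_prominence_mm`
#' prominence (height above the highest saddle connecting the peak to a
#' larger one) and at least `min_separation_s` between retained peaks (taller
#' peaks win). Per-peak depth is the local maximum; the window rate is
#' 60 * (n_peaks - 1) / (t_last - t_first).
#'
#' @param man Manikin stream (tibble `time_s`, `depth_mm`).
#' @param min_prominence_mm Minimum peak prominence, mm.
#' @param min_separation_s Minimum time between peaks, s.
#' @return A `cpr_cycles` list: `peaks` (tibble `time_s`, `depth_mm`),
#'   `rate_cpm` (NA and `flagged = TRUE` when fewer than 2 peaks),
#'   `mean_depth_mm`, `n_cycles`, `flagged`.
#' @export
detect_cycles <- function(man, min_prominence_mm = 10, min_separation_s = 0.25) {
  man <- validate_manikin_stream(man)
  man <- man[order(man$time_s), ]
  idx <- find_peaks(man$depth_mm, min_prominence_mm,
                    min_sep = min_separation_s / stats::median(diff(man$time_s)))
  peaks <- tibble::tibble(time_s = man$time_s[idx], depth_mm = man$depth_mm[idx])
  n <- nrow(peaks)
  rate <- if (n >= 2) 60 * (n - 1) / (peaks$time_s[n] - peaks$time_s[1]) else NA_real_
  structure(list(peaks = peaks,
                 rate_cpm = rate,
                 mean_depth_mm = if (n > 0) mean(peaks$depth_mm) else NA_real_,
                 n_cycles = n,
                 flagged = n < 2),
            class = "cpr_cycles")
}

#' @export
print.cpr_cycles <- function(x, ...) {
  cat(sprintf("%d compression cycles; mean depth %.1f mm; rate %.1f cpm%s\n",
              x$n_cycles, x$mean_depth_mm, x$rate_cpm,
              if (x$flagged) " [flagged: rate undefined]" else ""))
  invisible(x)
}

#' Assemble the per-minute feature table from the two streams
#'
#' Synchronizes the streams (unless `lag_s` is supplied), then for each
#' complete minute m computes: the kinematic features (window means of the
#' pose angles; C7-Th1 path length and 95% ellipse area in the horizontal
#' plane) on the first `kin_window_s` seconds of the minute, and the
#' compression depth/rate from cycle detection over the full minute. Trials
#' shorter than `duration` minutes yield fewer rows, never padded. Windows are
#' half-open `[start, end)`.
#'
#' @param kin Kinematic stream.
#' @param man Manikin stream.
#' @param threshold_mm Depth threshold for grouping, mm (see
#'   [group_by_depth()]).
#' @param kin_window_s Length of the kinematic sub-window at the start of each
#'   minute, s.
#' @param lag_s Known clock offset; `NULL` (default) estimates it with
#'   [synchronize()].
#' @param sensor_map Sensor mapping for [extract_pose_series()].
#' @param smooth_window Optional moving-average window (frames) applied to the
#'   C7-Th1 trajectory before the sway metrics; 0 disables smoothing.
#' @param ellipse_method Passed to [ellipse_area_95()].
#' @return A tibble with columns `minute_idx`, `depth_mm`, `rate_cpm`,
#'   `pl_mm`, `ea_mm2`, `lkfa`, `rkfa`, `lefa`, `refa`, `trunk_incl`,
#'   `alpha_dev`, `group`; attribute `lag_s` records the synchronization.
#' @export
build_feature_table <- function(kin, man, threshold_mm = 40, kin_window_s = 30,
                                lag_s = NULL, sensor_map = default_sensor_map(),
                                smooth_window = 0,
                                ellipse_method = c("chi2", "quantile")) {
  ellipse_method <- match.arg(ellipse_method)
  kin <- validate_kinematic_stream(kin)
  man <- validate_manikin_stream(man)
  if (is.null(lag_s)) lag_s <- synchronize(kin, man)
  man$time_s <- man$time_s - lag_s

  t0 <- min(kin$time_s)
  dur <- min(max(kin$time_s), max(man$time_s)) - t0
  n_min <- floor(dur / 60)
  if (n_min < 1) {
    stop("synchronized streams cover less than one full minute", call. = FALSE)
  }

  pose <- extract_pose_series(kin, sensor_map)
  c7 <- kin[kin$sensor_id == sensor_map[["c7th1"]], ]
  c7 <- c7[order(c7$time_s), ]

  rows <- purrr::map(seq_len(n_min), function(m) {
    a <- t0 + 60 * (m - 1)
    pw <- pose[pose$time_s >= a & pose$time_s < a + kin_window_s, ]
    cw <- c7[c7$time_s >= a & c7$time_s < a + kin_window_s,
             c("x_mm", "y_mm", "z_mm")]
    if (smooth_window > 1) {
      cw <- dplyr::mutate(cw, dplyr::across(
        dplyr::everything(),
        ~ stats::filter(.x, rep(1 / smooth_window, smooth_window), sides = 2)
      ))
      cw <- cw[stats::complete.cases(cw), ]
    }
    traj <- project_trajectory(cw, "horizontal")
    ell_area <- tryCatch(ellipse_area_95(traj, ellipse_method)$area_mm2,
                         error = function(e) NA_real_)
    mw <- man[man$time_s >= a & man$time_s < a + 60, ]
    cyc <- detect_cycles(mw)
    tibble::tibble(
      minute_idx = m,
      depth_mm = cyc$mean_depth_mm,
      rate_cpm = cyc$rate_cpm,
      pl_mm = path_length(traj),
      ea_mm2 = ell_area,
      lkfa = mean(pw$lkfa, na.rm = TRUE),
      rkfa = mean(pw$rkfa, na.rm = TRUE),
      lefa = mean(pw$lefa, na.rm = TRUE),
      refa = mean(pw$refa, na.rm = TRUE),
      trunk_incl = mean(pw$trunk_incl, na.rm = TRUE),
      alpha_dev = mean(pw$alpha_dev, na.rm = TRUE)
    )
  })
  out <- group_by_depth(dplyr::bind_rows(rows), threshold_mm)
  attr(out, "lag_s") <- as.numeric(lag_s)
  out
}

#' Label feature rows by depth threshold
#'
#' Partitions the per-interval rows into the `deep` group (mean compression
#' depth at or above the threshold) and the `shallow` group (below it). The
#' default threshold is 40 mm; 50 mm matches the guideline target.
#'
#' @param table Feature table with a `depth_mm` column.
#' @param threshold_mm Grouping threshold, mm; the boundary value is `deep`.
#' @return The table with a `group` factor column (`deep`, `shallow`).
#' @export
group_by_depth <- function(table, threshold_mm = 40) {
  if (!"depth_mm" %in% names(table)) {
    stop("feature table lacks a depth_mm column", call. = FALSE)
  }
  dplyr::mutate(table, group = factor(
    ifelse(.data$depth_mm >= threshold_mm, "deep", "shallow"),
    levels = c("deep", "shallow")
  ))
}

# local maxima with prominence and minimum-separation filtering
find_peaks <- function(x, min_prominence, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- vapply(cand, function(i) {
    higher_l <- which(x[seq_len(i - 1)] > x[i])
    higher_r <- which(x[(i + 1):n] > x[i]) + i
    lo <- if (length(higher_l)) max(higher_l) else 1L
    hi <- if (length(higher_r)) min(higher_r) else n
    saddle <- max(min(x[lo:i]), min(x[i:hi]))
    (x[i] - saddle) >= min_prominence
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) < 2) return(cand)
  # greedy by height: taller peaks suppress close smaller ones
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(i - kept) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}
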