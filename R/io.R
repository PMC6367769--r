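# Stream readers/writers. Interchange formats are deliberately plain:
# long-form CSV for the sensor stream, two-column CSV for the manikin log,
# TSV for feature tables, JSON for analysis reports. "." decimal and ","
# field separators are fixed to avoid locale drift.

#' Read a kinematic sensor stream from CSV
#'
#' Expects header `time_s,sensor_id,x_mm,y_mm,z_mm`, one row per sensor per
#' frame. Validates column presence, numeric cells and per-sensor
#' non-decreasing timestamps. Sensor ids outside [default_sensor_map()] are
#' kept but warned about.
#'
#' @param path CSV file path.
#' @return A tibble kinematic stream.
#' @export
read_kinematic_stream <- function(path) {
  need <- c("time_s", "sensor_id", "x_mm", "y_mm", "z_mm")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(need, hdr)
  if (length(miss) > 0) {
    stop("kinematic stream is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), sensor_id = readr::col_character(),
    x_mm = readr::col_double(), y_mm = readr::col_double(),
    z_mm = readr::col_double()
  )))
  stop_on_parse_problems(df, path)
  unknown <- setdiff(unique(df$sensor_id), unname(default_sensor_map()))
  if (length(unknown) > 0) {
    warning("unknown sensor ids (kept): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  bad <- df |>
    dplyr::group_by(.data$sensor_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_s), .groups = "drop")
  if (any(!bad$ok)) {
    stop("timestamps decrease within sensor(s): ",
         paste(bad$sensor_id[!bad$ok], collapse = ", "), call. = FALSE)
  }
  validate_kinematic_stream(df)
}

#' Read a manikin depth stream from CSV
#'
#' Expects header `time_s,depth_mm`. Negative depths are rejected with the
#' offending row number; an all-zero signal is valid but flagged with a
#' warning (no compressions).
#'
#' @param path CSV file path.
#' @return A tibble manikin stream.
#' @export
read_manikin_stream <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(c("time_s", "depth_mm"), hdr)
  if (length(miss) > 0) {
    stop("manikin stream is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), depth_mm = readr::col_double()
  )))
  stop_on_parse_problems(df, path)
  if (any(df$depth_mm < 0)) {
    stop("negative depth at row ", which(df$depth_mm < 0)[1], call. = FALSE)
  }
  if (all(df$depth_mm == 0)) {
    warning("manikin stream contains no compressions (all-zero depth)",
            call. = FALSE)
  }
  validate_manikin_stream(df)
}

#' @rdname read_kinematic_stream
#' @param stream Stream tibble to write.
#' @export
write_kinematic_stream <- function(stream, path) {
  out <- validate_kinematic_stream(stream)
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric), fmt_num))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_manikin_stream
#' @param stream Stream tibble to write.
#' @export
write_manikin_stream <- function(stream, path) {
  out <- validate_manikin_stream(stream)
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric), fmt_num))
  readr::write_csv(out, path)
  invisible(path)
}

# fixed decimal format (nanometre/nanosecond scale), idempotent under
# write -> read -> write so stream files round-trip bit-identically
fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.9f", x))

#' Read/write a per-minute feature table (TSV)
#'
#' @param path TSV file path.
#' @return A feature-table tibble.
#' @export
read_feature_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stop_on_parse_problems(df, path)
  if ("group" %in% names(df)) {
    df$group <- factor(df$group, levels = c("deep", "shallow"))
  }
  df
}

#' @rdname read_feature_table
#' @param table Feature table to write.
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Run the full analysis pipeline on one simulated trial
#'
#' Simulate -> synchronize -> per-minute features -> group comparisons and
#' standardized regression -> write a JSON report plus the TSV feature table.
#' Each stage and every decision flag (estimated lag, threshold, seed) is
#' echoed into the report for auditability.
#'
#' A 10-minute trial yields only 10 feature rows — far too few for a stable
#' regression — so per-row analyses across many simulated trials (or the
#' feature-level generator) are the intended input for [standardized_ols()];
#' the regression block is included here when `n >= 8` rows are available and
#' skipped (with a note) otherwise.
#'
#' @param cfg A `cpr_trial_config`; the trial to simulate and analyse.
#' @param out_dir Output directory (created if needed).
#' @param threshold_mm Depth grouping threshold, mm.
#' @param compare Features to compare across groups when both groups occur.
#' @return Invisibly, a list with `report_path`, `table_path` and the parsed
#'   report.
#' @export
run_cpr_pipeline <- function(cfg, out_dir, threshold_mm = 40,
                             compare = c("pl_mm", "ea_mm2", "lkfa", "lefa")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial <- generate_trial(cfg)
  tab <- build_feature_table(trial$kinematic, trial$manikin,
                             threshold_mm = threshold_mm)
  table_path <- file.path(out_dir, "feature_table.tsv")
  write_feature_table(tab, table_path)

  comparisons <- list()
  if (nlevels(droplevels(tab$group)) == 2) {
    comparisons <- lapply(compare, function(f) {
      as.list(tidy(compare_groups(tab, f)))
    })
    names(comparisons) <- compare
  }

  regression <- NULL
  ok <- stats::complete.cases(tab[, c("rate_cpm", "pl_mm", "lkfa", "lefa", "depth_mm")])
  if (sum(ok) >= 8) {
    fit <- standardized_ols(tab[ok, c("rate_cpm", "pl_mm", "lkfa", "lefa")],
                            tab$depth_mm[ok])
    regression <- list(terms = as.list(tidy(fit)), model = as.list(glance(fit)))
  }

  report <- list(
    config = list(rate_cpm = cfg$rate_cpm, depth_mm = cfg$depth_mm,
                  duration_s = cfg$duration_s, sample_hz = cfg$sample_hz,
                  noise_sd_mm = cfg$noise_sd_mm, sway_amp_mm = cfg$sway_amp_mm,
                  depth_cv = cfg$depth_cv, clock_offset_s = cfg$clock_offset_s,
                  seed = cfg$seed, threshold_mm = threshold_mm,
                  manikin_resistance_n_cm2 = cfg$manikin_resistance_n_cm2),
    synchronization = list(lag_s = attr(tab, "lag_s")),
    n_minutes = nrow(tab),
    group_sizes = as.list(table(tab$group)),
    comparisons = comparisons,
    regression = if (is.null(regression))
      "skipped: fewer than 8 complete rows" else regression
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(report_path = report_path, table_path = table_path,
                 report = report))
}

# --- shared validators ------------------------------------------------------

validate_kinematic_stream <- function(stream) {
  need <- c("time_s", "sensor_id", "x_mm", "y_mm", "z_mm")
  if (!is.data.frame(stream) || !all(need %in% names(stream))) {
    stop("kinematic stream needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  num <- c("time_s", "x_mm", "y_mm", "z_mm")
  bad <- num[!vapply(stream[num], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric kinematic columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(stream)
}

validate_manikin_stream <- function(stream) {
  if (!is.data.frame(stream) || !all(c("time_s", "depth_mm") %in% names(stream))) {
    stop("manikin stream needs columns: time_s, depth_mm", call. = FALSE)
  }
  if (!is.numeric(stream$time_s) || !is.numeric(stream$depth_mm)) {
    stop("manikin stream columns must be numeric", call. = FALSE)
  }
  tibble::as_tibble(stream)
}

stop_on_parse_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    stop("non-numeric or malformed cell in ", path, " at row ", pr$row[1],
         call. = FALSE)
  }
}
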