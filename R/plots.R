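#' Plot extracted pose angles over time
#'
#' One panel per angular feature, useful for eyeballing drift, sway
#' perturbation and flagged frames.
#'
#' @param object A pose series from [extract_pose_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot cpr_pose_series
autoplot.cpr_pose_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, -"flagged"),
    -"time_s", names_to = "feature", values_to = "degrees"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$degrees)) +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (degrees)")
}

#' Compare a feature across depth groups
#'
#' Box plot of one feature for the deep versus shallow compression groups of
#' a per-minute feature table.
#'
#' @param table Feature table with a `group` column (see [group_by_depth()]).
#' @param feature Column to plot.
#' @return A ggplot object.
#' @export
plot_feature_groups <- function(table, feature = "pl_mm") {
  if (!all(c(feature, "group") %in% names(table))) {
    stop("table needs columns '", feature, "' and 'group'", call. = FALSE)
  }
  ggplot2::ggplot(table, ggplot2::aes(x = .data$group,
                                      y = .data[[feature]],
                                      fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(deep = "#2166ac", shallow = "#b2182b")) +
    ggplot2::labs(x = "compression-depth group", y = feature)
}
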