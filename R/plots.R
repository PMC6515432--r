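# ggplot2 helpers for traces and comparison results.

#' Plot detrended traces with their AsLS baselines
#'
#' @param detrended Detrended trace tibble from [detrend_asls()].
#' @param cells Optional cell IDs to show (default: first 4).
#' @return A ggplot: raw trace, estimated baseline, and corrected trace,
#'   faceted by cell, x in minutes.
#' @export
plot_trace <- function(detrended, cells = NULL) {
  if (is.null(cells)) cells <- head(unique(detrended$cell_id), 4)
  df <- detrended |>
    dplyr::filter(.data$cell_id %in% cells) |>
    dplyr::mutate(minutes = .data$frame * .data$frame_interval / 60) |>
    tidyr::pivot_longer(cols = c("raw", "baseline", "value"),
                        names_to = "series", values_to = "intensity") |>
    dplyr::mutate(series = factor(.data$series, levels = c("raw", "baseline", "value"),
                                  labels = c("raw", "AsLS baseline", "corrected")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minutes, y = .data$intensity,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~cell_id, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "fluorescence (AU)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Effect-size plot for a set of group comparisons
#'
#' Cohen's d per metric, filled by the joint significance call (adjusted
#' p < alpha and |d| > d_min).
#'
#' @param object A `ca_comparisons` tibble ([run_comparison_design()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ca_comparisons <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$cohens_d))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric_name, y = .data$cohens_d,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-0.2, 0.2), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cohen's d (group A - group B)",
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' Spike-rate distributions by group
#'
#' @param joined Joined phenotype table with a grouping column.
#' @param group_col Column defining the two groups (e.g. `marker` or a
#'   positivity call).
#' @param thresholds A [spike_thresholds()] giving which spike-rate columns to
#'   show.
#' @return A ggplot of per-cell spikes/h by threshold multiplier and group.
#' @export
plot_spike_rates <- function(joined, group_col = "marker",
                             thresholds = spike_thresholds()) {
  cols <- intersect(spike_col_names(thresholds$multipliers), names(joined))
  df <- joined |>
    tidyr::pivot_longer(cols = dplyr::all_of(cols),
                        names_to = "threshold", values_to = "spikes_per_hour") |>
    dplyr::mutate(threshold = factor(.data$threshold, levels = cols))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$spikes_per_hour,
                                   fill = .data[[group_col]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "spike threshold (x baseline)", y = "spikes per hour",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
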