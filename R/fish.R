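# Plate-normalized FISH scores (F/F0) and marker-positivity calls, joined to
# calcium cells through the ROI co-registration map.

#' Compute plate-normalized FISH scores and positivity calls
#'
#' Each cell's FISH mean intensity F is normalized by the plate background F0,
#' the average of the five dimmest cells on the same plate, giving the
#' dimensionless FISH score F/F0. A cell is called positive for the marker at
#' multiplier `m` when its score is at least `m`; the default thresholds are
#' 200% (the primary positivity call), 300% and 400% of background.
#'
#' @param fish FISH intensity tibble from [read_fish_table()]: columns
#'   `plate_id`, `fish_roi_id`, `mean_intensity`. Scores are computed within
#'   each plate.
#' @param expression_thresholds Positivity multipliers; default `c(2, 3, 4)`.
#' @param background_n Number of dimmest cells averaged into F0; default 5.
#'   Ties among the dimmest are broken by (intensity, ROI ID) so F0 is
#'   deterministic.
#' @return A tibble with columns `plate_id`, `fish_roi_id`, `mean_intensity`,
#'   `background`, `fish_score`, and one logical `positive_<m>x` column per
#'   threshold. All cells are scored, including the background cells
#'   themselves (scores below 1 are legitimate).
#' @examples
#' fish <- tibble::tibble(plate_id = "p1", fish_roi_id = as.character(1:6),
#'                        mean_intensity = c(8, 9, 10, 11, 12, 25))
#' compute_fish_scores(fish)
#' @export
compute_fish_scores <- function(fish, expression_thresholds = c(2, 3, 4),
                                background_n = 5) {
  stopifnot(all(c("plate_id", "fish_roi_id", "mean_intensity") %in% names(fish)),
            length(expression_thresholds) >= 1, all(expression_thresholds > 0),
            background_n >= 1)
  if (any(fish$mean_intensity < 0)) abort("negative mean_intensity")
  fish |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(function(tbl, key) {
      if (nrow(tbl) < background_n) {
        abort(sprintf("plate '%s' has %d cells; need >= %d for background F0",
                      key$plate_id, nrow(tbl), background_n))
      }
      ord <- order(tbl$mean_intensity, tbl$fish_roi_id)
      f0 <- mean(tbl$mean_intensity[ord[seq_len(background_n)]])
      if (f0 <= 0) abort(sprintf("degenerate background on plate '%s': F0 = %g",
                                 key$plate_id, f0))
      score <- tbl$mean_intensity / f0
      pos <- purrr::map(expression_thresholds, function(m) score >= m)
      names(pos) <- positive_col_names(expression_thresholds)
      dplyr::bind_cols(tbl, tibble(background = f0, fish_score = score), tibble(!!!pos))
    }) |>
    dplyr::ungroup()
}

positive_col_names <- function(thresholds) {
  sprintf("positive_%sx", format(thresholds, trim = TRUE, drop0trailing = TRUE))
}

#' Join calcium metrics to FISH phenotype scores
#'
#' Inner join of per-cell activity metrics and FISH records through the ROI
#' co-registration map (calcium ROI ID to FISH ROI ID). Cells present on only
#' one side are counted and reported, never silently dropped into the joined
#' rows.
#'
#' @param metrics Cell metrics tibble from [compute_cell_metrics()] (keyed by
#'   `cell_id` = calcium ROI ID).
#' @param fish FISH score tibble from [compute_fish_scores()] (keyed by
#'   `fish_roi_id`).
#' @param roi_map Tibble with columns `calcium_roi_id`, `fish_roi_id`;
#'   must be one-to-one.
#' @param quiet Suppress the unmatched-cell message.
#' @return The joined tibble (one row per matched cell, metrics plus
#'   `fish_score` and positivity calls), with an `unmatched` attribute:
#'   a list of `n_metrics_unmatched`, `n_fish_unmatched`, and the IDs.
#' @export
join_phenotype <- function(metrics, fish, roi_map, quiet = FALSE) {
  stopifnot("cell_id" %in% names(metrics), "fish_roi_id" %in% names(fish),
            all(c("calcium_roi_id", "fish_roi_id") %in% names(roi_map)))
  validate_roi_map(roi_map)
  joined <- metrics |>
    dplyr::inner_join(roi_map, by = c(cell_id = "calcium_roi_id")) |>
    dplyr::inner_join(fish, by = "fish_roi_id")
  un_metrics <- setdiff(metrics$cell_id, joined$cell_id)
  un_fish <- setdiff(fish$fish_roi_id, joined$fish_roi_id)
  if (!quiet && (length(un_metrics) || length(un_fish))) {
    message(sprintf("join_phenotype: %d metric cell(s) and %d FISH cell(s) unmatched",
                    length(un_metrics), length(un_fish)))
  }
  attr(joined, "unmatched") <- list(
    n_metrics_unmatched = length(un_metrics),
    n_fish_unmatched = length(un_fish),
    metrics_cell_ids = un_metrics,
    fish_roi_ids = un_fish
  )
  joined
}
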