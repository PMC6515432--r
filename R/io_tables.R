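# CSV interchange: trace tables (frame x cell), FISH intensity tables,
# ROI co-registration maps, and result reports. All comma-delimited with a
# header row; frame indices are 0-based; empty cells mark untracked frames
# (zero is a legal intensity).

#' Read a per-cell fluorescence trace table
#'
#' Parses a CSV exported from ROI tracking: the first column is the frame
#' index (0-based), every remaining column one cell's fluorescence, the header
#' row the cell IDs. Empty cells mark frames where the cell was not tracked.
#'
#' @param path Path to the CSV file.
#' @param frame_interval Seconds between frames. Default 8 s (0.125 Hz), the
#'   acquisition rate the pipeline assumes for a 2 h / 900 frame recording.
#' @return A tibble in long format with columns `cell_id`, `frame` (0-based
#'   integer), `value` (fluorescence, `NA` when untracked), `valid` (logical),
#'   and `frame_interval` (seconds). Cells appear in the file's column order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("frame,c1,c2", "0,10,20", "1,,21", "2,12,22"), f)
#' read_trace_table(f)
#' @export
read_trace_table <- function(path, frame_interval = 8) {
  stopifnot(is.numeric(frame_interval), frame_interval > 0)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2) {
    abort("trace table needs a frame column plus at least one cell column")
  }
  cell_ids <- names(raw)[-1]
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate cell ID(s) in trace table: ", paste(dup, collapse = ", ")))
  }
  frame <- parse_numeric_column(raw[[1]], names(raw)[1], allow_blank = FALSE)
  out <- purrr::map_dfr(seq_along(cell_ids), function(j) {
    v <- parse_numeric_column(raw[[j + 1]], cell_ids[j], allow_blank = TRUE)
    tibble(
      cell_id = cell_ids[j],
      frame = as.integer(frame),
      value = v,
      valid = !is.na(v),
      frame_interval = frame_interval
    )
  })
  out$cell_id <- factor(out$cell_id, levels = cell_ids)
  dplyr::arrange(out, .data$cell_id, .data$frame) |>
    dplyr::mutate(cell_id = as.character(.data$cell_id))
}

# Parse a character column to numeric; blanks -> NA when allowed, any other
# unparseable entry is an error naming the row and column.
parse_numeric_column <- function(x, colname, allow_blank = TRUE) {
  x <- trimws(x)
  blank <- is.na(x) | x == ""
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!blank & is.na(v))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric value '%s' at row %d, column '%s'",
                  x[bad[1]], bad[1], colname))
  }
  if (!allow_blank && any(blank)) {
    abort(sprintf("blank value at row %d, column '%s'", which(blank)[1], colname))
  }
  v
}

#' Read a FISH mean-intensity table
#'
#' @param path CSV with columns `fish_roi_id` and `mean_intensity`.
#' @param plate_id Plate identifier; FISH background (F0) is computed per
#'   plate, so every intensity table must name its plate.
#' @return A tibble with columns `plate_id`, `fish_roi_id`, `mean_intensity`.
#'   All rows are retained, including dim background cells (intensity 0 is
#'   legitimate).
#' @export
read_fish_table <- function(path, plate_id) {
  stopifnot(is.character(plate_id), length(plate_id) == 1)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("fish_roi_id", "mean_intensity")) {
    if (!col %in% names(raw)) {
      abort(sprintf("FISH table is missing required column '%s'", col))
    }
  }
  if (nrow(raw) < 1) abort("FISH table has no rows")
  intensity <- parse_numeric_column(raw$mean_intensity, "mean_intensity", allow_blank = FALSE)
  if (any(intensity < 0)) {
    abort(sprintf("negative mean_intensity at row %d", which(intensity < 0)[1]))
  }
  tibble(
    plate_id = plate_id,
    fish_roi_id = as.character(raw$fish_roi_id),
    mean_intensity = intensity
  )
}

#' Read an ROI co-registration map
#'
#' @param path CSV with columns `calcium_roi_id` and `fish_roi_id`, one row
#'   per co-registered cell.
#' @return A tibble with the two ID columns. The mapping must be one-to-one;
#'   duplicated IDs on either side are an error.
#' @export
read_roi_map <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("calcium_roi_id", "fish_roi_id")) {
    if (!col %in% names(raw)) {
      abort(sprintf("ROI map is missing required column '%s'", col))
    }
  }
  map <- tibble(calcium_roi_id = as.character(raw$calcium_roi_id),
                fish_roi_id = as.character(raw$fish_roi_id))
  validate_roi_map(map)
  map
}

validate_roi_map <- function(map) {
  for (col in c("calcium_roi_id", "fish_roi_id")) {
    dup <- unique(map[[col]][duplicated(map[[col]])])
    if (length(dup) > 0) {
      abort(paste0("ROI map is not one-to-one; duplicated ", col, ": ",
                   paste(dup, collapse = ", ")))
    }
  }
  invisible(map)
}

#' Write a result report to CSV
#'
#' Writes per-cell metric tables or group-comparison tables as plain CSV with
#' stable column names; values round-trip through [read_report()] to full
#' double precision.
#'
#' @param results A non-empty data frame (e.g. the output of
#'   [compute_cell_metrics()] or [run_comparison_design()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("results must be a non-empty data frame")
  }
  readr::write_csv(results, path, progress = FALSE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path CSV path.
#' @return A tibble with column types guessed from the data.
#' @export
read_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
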