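# Config-driven orchestration: ingest -> contiguity filter -> detrend ->
# metrics -> FISH join -> comparison designs -> randomization controls ->
# CSV reports + JSON manifest.

#' Read a pipeline run configuration
#'
#' @param path YAML file. Recognized keys: `paths` (`trace`, `fish`,
#'   `roi_map`, optional `markers`, `output_dir`), `stage_label`, `seed`,
#'   `frame_interval`, and the per-module keys `preprocess` (`min_frames`,
#'   `smoothness`, `asymmetry`, `max_iter`), `metrics` (`thresholds`,
#'   `min_duration_frames`, `n_states`, `order`, `min_window`, `power_mode`),
#'   `fish` (`expression_thresholds`, `background_n`, `plate_id`), `stats`
#'   (`alpha`, `d_min`, `n_shuffle_seeds`, `shuffle_replace`), `designs`
#'   (list of `{type, markers, expression_threshold}`).
#' @param overrides Named list merged over the file contents (one level of
#'   module nesting, e.g. `list(stats = list(alpha = 0.01))`).
#' @return A config list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- modify_deep(cfg, overrides)
  defaults <- list(
    stage_label = "stage",
    seed = 1L,
    frame_interval = 8,
    paths = list(),
    preprocess = list(min_frames = 600, smoothness = 1e5, asymmetry = 0.01, max_iter = 10),
    metrics = list(thresholds = c(1.25, 1.5, 2, 3, 4, 8), min_duration_frames = 2,
                   n_states = 4, order = 1, min_window = 16, power_mode = "fluctuation"),
    fish = list(expression_thresholds = c(2, 3, 4), background_n = 5, plate_id = "plate1"),
    stats = list(alpha = 0.05, d_min = 0.2, n_shuffle_seeds = 1, shuffle_replace = TRUE),
    designs = list()
  )
  cfg <- modify_deep(defaults, cfg)
  structure(cfg, class = c("run_config", "list"))
}

modify_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) && !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Ingests the trace, FISH and ROI-map CSVs named in the config, applies the
#' contiguity filter and AsLS detrending, computes the four activity metrics
#' per cell, scores and joins the FISH phenotype, runs the configured
#' comparison designs and the expression-level correlations, and writes every
#' result table as CSV plus a JSON manifest recording the config, seed,
#' package version and cell counts at each filtering step. A rerun with the
#' same config and seed reproduces every value.
#'
#' @param config A `run_config` (see [read_run_config()]) or path to a YAML
#'   file.
#' @return Invisibly, a list with the result tibbles (`metrics`,
#'   `fish_scores`, `joined`, `comparisons`, `correlations`) and the
#'   `manifest` list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$paths
  for (key in c("trace", "fish", "roi_map", "output_dir")) {
    if (is.null(p[[key]])) abort(sprintf("config paths$%s is required", key))
  }
  if (!dir.exists(p$output_dir)) dir.create(p$output_dir, recursive = TRUE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(packageVersion("caflux")),
                   counts = list(), complete = FALSE)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$complete <<- FALSE
      write_manifest(manifest, p$output_dir)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  traces <- step("ingest", read_trace_table(p$trace, frame_interval = config$frame_interval))
  manifest$counts$cells_ingested <- length(unique(traces$cell_id))

  filt <- step("contiguity_filter",
               filter_contiguous_tracks(traces, min_frames = config$preprocess$min_frames))
  manifest$counts$cells_kept <- length(unique(filt$kept$cell_id))
  manifest$counts$cells_dropped <- nrow(filt$dropped)
  if (manifest$counts$cells_kept == 0) {
    manifest$counts$note <- "0 cells retained by the contiguity filter"
    empty <- tibble(cell_id = character())
    write_manifest(modify_deep(manifest, list(complete = TRUE)), p$output_dir)
    readr::write_csv(empty, file.path(p$output_dir, "cell_metrics.csv"), progress = FALSE)
    return(invisible(list(metrics = empty, fish_scores = NULL, joined = NULL,
                          comparisons = NULL, correlations = NULL,
                          manifest = manifest)))
  }

  detr <- step("detrend", detrend_asls(filt$kept,
                                       smoothness = config$preprocess$smoothness,
                                       asymmetry = config$preprocess$asymmetry,
                                       max_iter = config$preprocess$max_iter))
  thr <- spike_thresholds(config$metrics$thresholds, config$metrics$min_duration_frames)
  metrics <- step("metrics", compute_cell_metrics(
    detr, thresholds = thr, n_states = config$metrics$n_states,
    order = config$metrics$order, min_window = config$metrics$min_window,
    power_mode = config$metrics$power_mode))
  write_report(metrics, file.path(p$output_dir, "cell_metrics.csv"))

  fish_tbl <- step("fish_scores", {
    fish_raw <- read_fish_table(p$fish, plate_id = config$fish$plate_id)
    compute_fish_scores(fish_raw,
                        expression_thresholds = config$fish$expression_thresholds,
                        background_n = config$fish$background_n)
  })
  write_report(fish_tbl, file.path(p$output_dir, "fish_scores.csv"))

  joined <- step("join", {
    roi_map <- read_roi_map(p$roi_map)
    j <- join_phenotype(metrics, fish_tbl, roi_map, quiet = TRUE)
    if (!is.null(p$markers)) {
      mk <- readr::read_csv(p$markers, show_col_types = FALSE, progress = FALSE)
      j <- dplyr::left_join(j, mk, by = "cell_id")
    }
    j
  })
  manifest$counts$cells_joined <- nrow(joined)
  write_report(joined, file.path(p$output_dir, "joined_phenotype.csv"))

  comparisons <- NULL
  if (length(config$designs) > 0) {
    comparisons <- step("designs", purrr::map_dfr(config$designs, function(d) {
      res <- run_comparison_design(
        joined, design = d$type, markers = unlist(d$markers),
        expression_threshold = d$expression_threshold %||% 2,
        alpha = config$stats$alpha, d_min = config$stats$d_min)
      dplyr::mutate(res, design = d$type, stage = config$stage_label,
                    expression_threshold = d$expression_threshold %||% 2)
    }))
    write_report(comparisons, file.path(p$output_dir, "comparisons.csv"))
  }

  correlations <- step("correlation", {
    ms <- intersect(metric_column_names(thr), names(joined))
    purrr::map_dfr(ms, function(m) {
      tryCatch(tidy(correlate_expression(joined, m)),
               error = function(e) tibble(metric_name = m, pearson_r = NA_real_,
                                          gam_r2 = NA_real_, n = NA_integer_))
    })
  })
  write_report(correlations, file.path(p$output_dir, "correlations.csv"))

  manifest$complete <- TRUE
  write_manifest(manifest, p$output_dir)
  invisible(list(metrics = metrics, fish_scores = fish_tbl, joined = joined,
                 comparisons = comparisons, correlations = correlations,
                 manifest = manifest, detrended = detr))
}

write_manifest <- function(manifest, output_dir) {
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the randomization controls for a pipeline run
#'
#' Computes the shuffle control (Hurst and entropy on resampled traces) and,
#' when two marker tables are supplied, the FISH-label randomization control,
#' and writes both to the output directory with the seeds recorded.
#'
#' @param config A `run_config` or YAML path (needs `paths$output_dir`).
#' @param detrended Detrended trace tibble (e.g. `run_pipeline(...)$detrended`).
#' @param joined_a,joined_b Optional joined phenotype tables for the label
#'   randomization control.
#' @return Invisibly, a list with `shuffle` (a [shuffle_control()] result) and
#'   `label_randomization` (a `ca_comparisons` tibble or NULL).
#' @export
run_controls <- function(config, detrended, joined_a = NULL, joined_b = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$paths$output_dir
  if (is.null(out_dir)) abort("config paths$output_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sh <- shuffle_control(detrended,
                        n_seeds = config$stats$n_shuffle_seeds,
                        seed = config$seed,
                        replace = config$stats$shuffle_replace,
                        n_states = config$metrics$n_states,
                        order = config$metrics$order,
                        min_window = config$metrics$min_window)
  write_report(dplyr::mutate(sh$summary, seed = config$seed,
                             n_seeds = sh$n_seeds),
               file.path(out_dir, "shuffle_control.csv"))
  lr <- NULL
  if (!is.null(joined_a) && !is.null(joined_b)) {
    lr <- label_randomization_control(joined_a, joined_b, seed = config$seed,
                                      alpha = config$stats$alpha,
                                      d_min = config$stats$d_min)
    write_report(dplyr::mutate(lr, seed = config$seed),
                 file.path(out_dir, "label_randomization_control.csv"))
  }
  invisible(list(shuffle = sh, label_randomization = lr))
}
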