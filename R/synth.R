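# Seeded synthetic-data generator: fractional Gaussian noise, Poisson spike
# trains on a drifting baseline, and plate-level FISH intensity models with a
# dim background subpopulation. Every pipeline stage can be validated against
# the generator's ground truth.

#' Specification of one simulated cell population
#'
#' Defaults emulate the acquisition the pipeline targets: 2-hour recordings at
#' 0.125 Hz (900 frames of 8 s), a baseline of 100 fluorescence units with
#' slow linear drift of 20% of baseline over the recording, additive
#' long-memory noise (fractional Gaussian noise) of SD 5% of baseline, and
#' rectangular spike plateaus of at least 2 frames at controllable rate and
#' amplitude (multiples of baseline).
#'
#' @param n_cells Number of cells.
#' @param n_frames Frames per trace; default 900 (>= 600 keeps traces
#'   pipeline-compatible).
#' @param frame_interval Seconds per frame; default 8.
#' @param baseline_level Baseline fluorescence (arbitrary units); default 100.
#' @param drift_kind `"none"`, `"linear"` or `"exponential"`.
#' @param drift_magnitude Total drift over the recording as a fraction of
#'   baseline; default 0.2.
#' @param noise_sd Noise SD as a fraction of baseline; default 0.05.
#' @param hurst_index Hurst index of the fGn noise component in (0, 1);
#'   default 0.5 (white noise).
#' @param spike_rate_per_hour Mean Poisson spike rate; default 6.
#' @param spike_amplitude Length-2 range of spike plateau heights as multiples
#'   of baseline; default `c(1.25, 8)` spanning the analysis thresholds.
#' @param spike_duration_frames Length-2 integer range of spike durations
#'   (min >= 2); default `c(2, 5)`.
#' @param spike_shape `"rect"` (default; plateau, makes threshold-count ground
#'   truth exact) or `"decay"` (fast rise, exponential decay).
#' @param fish_positive_fraction Fraction of cells positive for the marker;
#'   default 0.8.
#' @param fish_positive_score_mean Mean FISH score (F/F0) of positive cells;
#'   default 3.
#' @param fish_background_cells Dim anchor cells added per plate (>= 5);
#'   default 5.
#' @param seed Integer seed; every draw is derived from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 50,
                           n_frames = 900,
                           frame_interval = 8,
                           baseline_level = 100,
                           drift_kind = c("linear", "none", "exponential"),
                           drift_magnitude = 0.2,
                           noise_sd = 0.05,
                           hurst_index = 0.5,
                           spike_rate_per_hour = 6,
                           spike_amplitude = c(1.25, 8),
                           spike_duration_frames = c(2, 5),
                           spike_shape = c("rect", "decay"),
                           fish_positive_fraction = 0.8,
                           fish_positive_score_mean = 3,
                           fish_background_cells = 5,
                           seed = 1) {
  drift_kind <- match.arg(drift_kind)
  spike_shape <- match.arg(spike_shape)
  stopifnot(n_cells >= 1, n_frames >= 16, frame_interval > 0, baseline_level > 0,
            drift_magnitude >= 0, noise_sd >= 0,
            hurst_index > 0, hurst_index < 1,
            spike_rate_per_hour >= 0,
            length(spike_amplitude) == 2, all(spike_amplitude > 1),
            length(spike_duration_frames) == 2, spike_duration_frames[1] >= 2,
            spike_duration_frames[2] >= spike_duration_frames[1],
            fish_positive_fraction >= 0, fish_positive_fraction <= 1,
            fish_background_cells >= 5)
  structure(list(
    n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, baseline_level = baseline_level,
    drift_kind = drift_kind, drift_magnitude = drift_magnitude,
    noise_sd = noise_sd, hurst_index = hurst_index,
    spike_rate_per_hour = spike_rate_per_hour,
    spike_amplitude = spike_amplitude,
    spike_duration_frames = as.integer(spike_duration_frames),
    spike_shape = spike_shape,
    fish_positive_fraction = fish_positive_fraction,
    fish_positive_score_mean = fish_positive_score_mean,
    fish_background_cells = as.integer(fish_background_cells),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Exact simulation of stationary fGn with the target autocovariance
#' `g(k) = 0.5 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})` via the Davies-Harte
#' circulant-embedding construction; unit marginal variance. If the circulant
#' eigenvalues are not all non-negative (possible for extreme n/H pairs), the
#' generator falls back to spectral synthesis with a warning.
#'
#' @param n Length (>= 16).
#' @param hurst_index Target H in (0, 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of length n.
#' @export
generate_fgn <- function(n, hurst_index, seed = NULL) {
  stopifnot(n >= 16, hurst_index > 0, hurst_index < 1)
  draw <- function() fgn_davies_harte(n, hurst_index)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

fgn_davies_harte <- function(n, H) {
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  ev <- Re(fft(c(g, g[n:2])))
  if (min(ev) < -1e-9) {
    warn("circulant embedding not positive semi-definite; falling back to spectral synthesis")
    return(fgn_spectral(n, H))
  }
  ev <- pmax(ev, 0)
  m <- 2L * n
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  z[1] <- complex(real = Re(z[1]) * sqrt(2), imaginary = 0)
  z[n + 1] <- complex(real = Re(z[n + 1]) * sqrt(2), imaginary = 0)
  z[(n + 2):m] <- Conj(z[seq(n, 2, -1)])
  Re(fft(sqrt(ev / (2 * m)) * z))[seq_len(n)]
}

# Approximate fGn via the fractional spectral density; used only when the
# circulant embedding fails.
fgn_spectral <- function(n, H) {
  freq <- pi * seq_len(n) / n
  dens <- freq^(1 - 2 * H)
  phase <- runif(n, 0, 2 * pi)
  amp <- sqrt(dens) * rnorm(n)
  x <- vapply(seq_len(n), function(t) sum(amp * cos(freq * t + phase)), numeric(1))
  as.numeric(scale(x))
}

#' Generate one synthetic fluorescence trace with ground truth
#'
#' Builds `baseline * (1 + drift(t)) + baseline * noise_sd * fGn(H)` plus
#' rectangular spike plateaus whose onsets follow a Poisson process at the
#' spec's rate; during a spike the trace is raised to `amplitude * baseline`.
#' Overlapping spikes are merged into a single run in the ground truth.
#' Reproducible given (spec seed, cell index).
#'
#' @param spec A [synthetic_spec()].
#' @param cell_index Cell number within the population (>= 1).
#' @param cell_id Optional ID; default `"cell<index>"`.
#' @return A list: `trace` (long tibble in the [read_trace_table()] layout)
#'   and `truth` (tibble of merged spike runs: `cell_id`, `onset_frame`,
#'   `duration_frames`, `amplitude`, plus per-cell `hurst_index` and
#'   `n_spikes_true`).
#' @export
generate_trace <- function(spec, cell_index, cell_id = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), cell_index >= 1)
  if (is.null(cell_id)) cell_id <- paste0("cell", cell_index)
  n <- spec$n_frames
  cell_seed <- (spec$seed %% 1000003L) * 2011L + as.integer(cell_index)
  withr::with_seed(cell_seed, {
    t_frac <- (seq_len(n) - 1) / (n - 1)
    drift <- switch(spec$drift_kind,
      none = rep(0, n),
      linear = spec$drift_magnitude * t_frac,
      exponential = spec$drift_magnitude * (exp(t_frac) - 1) / (exp(1) - 1)
    )
    noise <- if (spec$noise_sd > 0) {
      spec$baseline_level * spec$noise_sd * fgn_davies_harte(n, spec$hurst_index)
    } else rep(0, n)
    v <- spec$baseline_level * (1 + drift) + noise
    hours <- n * spec$frame_interval / 3600
    n_spikes <- rpois(1, spec$spike_rate_per_hour * hours)
    spike_mask <- rep(FALSE, n)
    spike_amp <- rep(NA_real_, n)
    if (n_spikes > 0) {
      max_dur <- spec$spike_duration_frames[2]
      onsets <- sample.int(max(1L, n - max_dur), n_spikes, replace = TRUE)
      dur_choices <- seq(spec$spike_duration_frames[1], spec$spike_duration_frames[2])
      for (s in seq_len(n_spikes)) {
        dur <- dur_choices[sample.int(length(dur_choices), 1)]
        amp <- runif(1, spec$spike_amplitude[1], spec$spike_amplitude[2])
        idx <- onsets[s]:min(n, onsets[s] + dur - 1)
        if (spec$spike_shape == "rect") {
          lvl <- amp * spec$baseline_level
          repl <- pmax(v[idx], lvl)
        } else {
          decay <- exp(-(seq_along(idx) - 1) / max(1, length(idx) / 2))
          repl <- pmax(v[idx], spec$baseline_level * (1 + (amp - 1) * decay))
        }
        v[idx] <- repl
        spike_mask[idx] <- TRUE
        spike_amp[idx] <- pmax(spike_amp[idx], amp, na.rm = TRUE)
      }
    }
    runs <- rle(spike_mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    truth_runs <- tibble(
      cell_id = cell_id,
      onset_frame = as.integer(starts[runs$values] - 1L),  # 0-based
      duration_frames = as.integer(runs$lengths[runs$values]),
      amplitude = vapply(which(runs$values), function(i) {
        max(spike_amp[starts[i]:ends[i]], na.rm = TRUE)
      }, numeric(1))
    )
    list(
      trace = tibble(cell_id = cell_id, frame = 0:(n - 1), value = v,
                     valid = TRUE, frame_interval = spec$frame_interval),
      truth = dplyr::mutate(truth_runs,
                            hurst_index = spec$hurst_index,
                            n_spikes_true = nrow(truth_runs))
    )
  })
}

#' Generate a whole population of traces
#'
#' @param spec A [synthetic_spec()].
#' @param label Prefix for cell IDs (also the population label in the truth
#'   table); default `"cell"`.
#' @return A list: `traces` (long tibble over all cells) and `truth` (one row
#'   per merged spike run plus per-cell summary columns, with a `population`
#'   column).
#' @export
generate_traces <- function(spec, label = "cell") {
  per_cell <- purrr::map(seq_len(spec$n_cells), function(i) {
    generate_trace(spec, i, cell_id = paste0(label, i))
  })
  traces <- purrr::map_dfr(per_cell, "trace")
  truth <- purrr::map_dfr(per_cell, "truth")
  cells <- tibble(cell_id = paste0(label, seq_len(spec$n_cells)),
                  population = label, hurst_index = spec$hurst_index)
  truth <- if (nrow(truth) > 0) {
    dplyr::left_join(cells, dplyr::select(truth, -"hurst_index"), by = "cell_id")
  } else {
    dplyr::mutate(cells, onset_frame = NA_integer_, duration_frames = NA_integer_,
                  amplitude = NA_real_, n_spikes_true = 0L)
  }
  truth$n_spikes_true[is.na(truth$n_spikes_true)] <- 0L
  list(traces = traces, truth = truth)
}

#' Generate a two-population dataset with FISH tables and ROI map
#'
#' Emulates a two-marker experiment: traces for populations A and B, a FISH
#' intensity table on one plate in which cells of each population are positive
#' for their own marker at the spec's `fish_positive_fraction`, a one-to-one
#' ROI map, a marker assignment table, and the generator's ground truth.
#' FISH intensities are log-normal (strictly positive, right-skewed, like
#' fluorescence data); `fish_background_cells` dim anchor cells are added per
#' plate so the five-dimmest background F0 is well defined.
#'
#' @param spec_a,spec_b [synthetic_spec()]s for the two populations.
#' @param labels Population / marker labels; default `c("A", "B")`.
#' @param plate_id Plate label; default `"plate1"`.
#' @param out_dir If non-NULL, writes `trace.csv` (wide frame x cell),
#'   `fish.csv`, `roimap.csv`, `markers.csv` and `truth.csv` there.
#' @return A list: `traces`, `fish`, `roi_map`, `markers`, `truth` (tibbles),
#'   and `paths` when `out_dir` was given.
#' @export
generate_population <- function(spec_a, spec_b, labels = c("A", "B"),
                                plate_id = "plate1", out_dir = NULL) {
  stopifnot(inherits(spec_a, "synthetic_spec"), inherits(spec_b, "synthetic_spec"),
            spec_a$n_cells + spec_b$n_cells >= 12, length(labels) == 2)
  pop_a <- generate_traces(spec_a, label = labels[1])
  pop_b <- generate_traces(spec_b, label = labels[2])
  traces <- dplyr::bind_rows(pop_a$traces, pop_b$traces)
  truth <- dplyr::bind_rows(pop_a$truth, pop_b$truth)
  cells <- unique(traces$cell_id)
  markers <- tibble(
    cell_id = cells,
    marker = rep(labels, c(spec_a$n_cells, spec_b$n_cells))
  )
  fish <- withr::with_seed(spec_a$seed * 31L + spec_b$seed, {
    bg_level <- 10
    score_for <- function(spec) {
      pos <- runif(spec$n_cells) < spec$fish_positive_fraction
      s <- numeric(spec$n_cells)
      s[pos] <- rlnorm(sum(pos), log(spec$fish_positive_score_mean), 0.15)
      s[!pos] <- rlnorm(sum(!pos), log(1.2), 0.15)
      s
    }
    scores <- c(score_for(spec_a), score_for(spec_b))
    n_bg <- max(spec_a$fish_background_cells, spec_b$fish_background_cells)
    tibble(
      plate_id = plate_id,
      fish_roi_id = c(paste0("f_", cells), paste0("bg", seq_len(n_bg))),
      mean_intensity = c(scores * bg_level,
                         bg_level * exp(rnorm(n_bg, 0, 0.02) - 0.05))
    )
  })
  roi_map <- tibble(calcium_roi_id = cells, fish_roi_id = paste0("f_", cells))
  out <- list(traces = traces, fish = fish, roi_map = roi_map,
              markers = markers, truth = truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wide <- traces |>
      dplyr::select("cell_id", "frame", "value") |>
      tidyr::pivot_wider(names_from = "cell_id", values_from = "value") |>
      dplyr::arrange(.data$frame)
    paths <- list(
      trace = file.path(out_dir, "trace.csv"),
      fish = file.path(out_dir, "fish.csv"),
      roi_map = file.path(out_dir, "roimap.csv"),
      markers = file.path(out_dir, "markers.csv"),
      truth = file.path(out_dir, "truth.csv")
    )
    readr::write_csv(wide, paths$trace, progress = FALSE)
    readr::write_csv(dplyr::select(fish, "fish_roi_id", "mean_intensity"),
                     paths$fish, progress = FALSE)
    readr::write_csv(roi_map, paths$roi_map, progress = FALSE)
    readr::write_csv(markers, paths$markers, progress = FALSE)
    readr::write_csv(truth, paths$truth, progress = FALSE)
    out$paths <- paths
  }
  out
}
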