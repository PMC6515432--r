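# Per-cell calcium activity metrics: multi-threshold spike frequency,
# average power, rescaled-range Hurst exponent, and Markovian entropy.

#' Spike threshold set
#'
#' @param multipliers Strictly increasing amplitude thresholds as multiples of
#'   the trace mean. Defaults to 125%, 150%, 200%, 300%, 400% and 800% of
#'   baseline.
#' @param min_duration_frames Minimum spike duration in frames (>= 2): a spike
#'   must span at least two consecutive time frames above threshold.
#' @return A list of class `spike_thresholds`.
#' @export
spike_thresholds <- function(multipliers = c(1.25, 1.5, 2, 3, 4, 8),
                             min_duration_frames = 2) {
  stopifnot(length(multipliers) >= 1, all(multipliers > 1),
            all(diff(multipliers) > 0), min_duration_frames >= 2)
  structure(list(multipliers = multipliers,
                 min_duration_frames = as.integer(min_duration_frames)),
            class = "spike_thresholds")
}

#' Count calcium spikes at multiple amplitude thresholds
#'
#' A spike is a maximal run of at least `min_duration_frames` consecutive
#' frames at or above `m` times the trace baseline, where the baseline is the
#' mean over all time points of the (detrended) trace. Runs separated by one
#' or more sub-threshold frames are distinct spikes. Single-frame excursions
#' are never spikes.
#'
#' @param values Numeric detrended trace.
#' @param frame_interval Seconds per frame (used to convert counts to rates).
#' @param thresholds A [spike_thresholds()] object.
#' @return A tibble with columns `multiplier`, `n_spikes`,
#'   `supra_frames` (frames at or above threshold), and `spikes_per_hour`.
#' @examples
#' v <- rep(100, 900); v[101:103] <- 250
#' count_spikes(v, frame_interval = 8)
#' @export
count_spikes <- function(values, frame_interval = 8, thresholds = spike_thresholds()) {
  stopifnot(inherits(thresholds, "spike_thresholds"),
            length(values) >= thresholds$min_duration_frames,
            frame_interval > 0)
  baseline <- mean(values)
  if (!is.finite(baseline) || baseline <= 0) {
    abort("trace baseline (mean) must be positive for percent-of-baseline thresholds")
  }
  hours <- length(values) * frame_interval / 3600
  purrr::map_dfr(thresholds$multipliers, function(m) {
    above <- values >= m * baseline
    r <- rle(above)
    n_spikes <- sum(r$values & r$lengths >= thresholds$min_duration_frames)
    tibble(multiplier = m,
           n_spikes = as.integer(n_spikes),
           supra_frames = as.integer(sum(above)),
           spikes_per_hour = n_spikes / hours)
  })
}

#' Average power of a trace
#'
#' Mean of squared values over the recording, `P = (1/T) * sum(X_i^2)`. In the
#' default `"fluctuation"` mode `X_i` is the mean-normalized fluctuation
#' `value_i / mean - 1`, which makes P dimensionless and comparable across
#' imaging sessions; `"raw"` mode squares the intensities themselves.
#'
#' @param values Numeric trace, non-empty.
#' @param mode `"fluctuation"` (default) or `"raw"`.
#' @return Non-negative scalar; 0 iff the fluctuation series is identically 0.
#' @export
average_power <- function(values, mode = c("fluctuation", "raw")) {
  mode <- match.arg(mode)
  stopifnot(length(values) >= 1, all(is.finite(values)))
  if (mode == "fluctuation") {
    m <- mean(values)
    if (m == 0) abort("zero-mean trace: fluctuation power undefined")
    x <- values / m - 1
  } else {
    x <- values
  }
  mean(x^2)
}

# Expected R/S of an i.i.d. Gaussian series of length n (Anis-Lloyd with
# Peters' (n - 1/2)/n correction); used to remove the small-sample bias of
# the rescaled-range slope.
expected_rs <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  s <- sum(sqrt((n - i) / i))
  front <- if (n <= 340) {
    gamma((n - 1) / 2) / (sqrt(pi) * gamma(n / 2))
  } else {
    (n * pi / 2)^(-0.5)
  }
  (n - 0.5) / n * front * s
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' Estimates long-range memory: H = 0.5 is memoryless, H > 0.5 persistent
#' (trend-following), H < 0.5 anti-persistent. For each dyadic window length
#' `L` in `min_window, 2*min_window, ...` up to half the trace, the series is
#' split into `floor(T/L)` non-overlapping windows; per window, R is the range
#' of the cumulative sum of mean-subtracted values and S the sample standard
#' deviation, and R/S is averaged over windows with S > 0. H is 0.5 plus the
#' OLS slope of `log2(mean R/S) - log2(E[R/S])` on `log2(L)`, where `E[R/S]`
#' is the expected rescaled range of an i.i.d. Gaussian series of length L
#' (Anis-Lloyd/Peters small-sample expectation); the correction removes the
#' upward finite-sample bias of the plain R/S slope on ~900-frame traces.
#'
#' @param values Numeric trace; length must allow at least 3 dyadic window
#'   lengths (>= 4 * `min_window`).
#' @param min_window Smallest window length; default 16.
#' @param window_base Window-length growth factor; default 2 (dyadic).
#' @return Scalar H estimate.
#' @export
hurst_rs <- function(values, min_window = 16, window_base = 2) {
  n <- length(values)
  stopifnot(min_window >= 4, window_base > 1)
  if (sd(values) == 0) abort("constant trace: rescaled range undefined (S = 0 everywhere)")
  lengths <- c()
  L <- min_window
  while (L <= n %/% 2) {
    lengths <- c(lengths, L)
    L <- L * window_base
  }
  if (length(lengths) < 3) {
    abort(sprintf("trace too short for R/S estimation: %d usable window lengths (need >= 3)",
                  length(lengths)))
  }
  mean_rs <- vapply(lengths, function(L) {
    k <- n %/% L
    rs <- vapply(seq_len(k), function(j) {
      w <- values[((j - 1) * L + 1):(j * L)]
      s <- sd(w)
      if (s == 0) return(NA_real_)
      cs <- cumsum(w - mean(w))
      (max(cs) - min(cs)) / s
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(mean_rs) & mean_rs > 0
  if (sum(ok) < 3) abort("fewer than 3 window lengths with positive R/S")
  e_rs <- vapply(lengths[ok], expected_rs, numeric(1))
  y <- log2(mean_rs[ok]) - log2(e_rs)
  x <- log2(lengths[ok])
  0.5 + unname(coef(lm(y ~ x))[2])
}

#' Markovian entropy of a trace
#'
#' Measures the predictability of the dynamics by treating the discretized
#' signal as a Markov chain: values are binned into `n_states` empirical
#' quantile states, an `n_states^order` x `n_states` transition count matrix
#' is built over `order`-step histories, each row is converted to transition
#' probabilities, the Shannon entropy `-sum(P_i log2 P_i)` of every row is
#' summed, and the sum is normalized by `n_states^order * log2(n_states)` so
#' the result lies in \[0, 1\]: 0 = fully predictable, 1 = maximally
#' unpredictable. Rows with no observed transitions contribute 0. Duplicate
#' quantile edges (low-variance traces) collapse states, so degenerate traces
#' score near 0 while the normalization keeps the nominal state count.
#'
#' @param values Numeric trace, length >= `n_states^order + 1`.
#' @param n_states Number of quantile states; default 4.
#' @param order Markov order k (history length); default 1.
#' @return Scalar in \[0, 1\].
#' @export
markovian_entropy <- function(values, n_states = 4, order = 1) {
  stopifnot(n_states >= 2, order >= 1)
  n <- length(values)
  if (n < n_states^order + 1) {
    abort(sprintf("trace length %d < n_states^order + 1 = %d", n, n_states^order + 1))
  }
  states <- quantile_states(values, n_states)
  n_hist <- n_states^order
  # encode each k-history as an integer in 1..n_states^order
  t_end <- n - order
  hist_code <- rep(0L, t_end)
  for (k in seq_len(order)) {
    hist_code <- hist_code * n_states + (states[seq_len(t_end) + k - 1L] - 1L)
  }
  hist_code <- hist_code + 1L
  nxt <- states[(order + 1):n]
  counts <- matrix(0, nrow = n_hist, ncol = n_states)
  idx <- (nxt - 1L) * n_hist + hist_code
  tab <- tabulate(idx, nbins = n_hist * n_states)
  counts[] <- tab
  row_ent <- apply(counts, 1, function(r) {
    tot <- sum(r)
    if (tot == 0) return(0)
    p <- r[r > 0] / tot
    -sum(p * log2(p))
  })
  sum(row_ent) / (n_hist * log2(n_states))
}

# Discretize into quantile states 1..n_states; duplicate quantile edges are
# collapsed (fewer occupied states), never an error.
quantile_states <- function(values, n_states) {
  probs <- seq_len(n_states - 1) / n_states
  edges <- unique(as.numeric(quantile(values, probs = probs, names = FALSE)))
  findInterval(values, edges, left.open = TRUE) + 1L
}

#' Compute all four activity metrics for every cell
#'
#' Bundles spike rates at each threshold, average power, the R/S Hurst
#' exponent, and the Markovian entropy into one row per cell. A metric whose
#' preconditions fail on a cell (e.g. a zero-variance trace for the Hurst
#' estimate) is recorded as `NA` with the reason appended to `notes`, never
#' silently as zero.
#'
#' @param detrended Detrended trace tibble from [detrend_asls()] (columns
#'   `cell_id`, `frame`, `value`, `frame_interval`).
#' @param thresholds A [spike_thresholds()] object.
#' @param n_states,order Markovian entropy parameters (defaults 4 quantile
#'   states, order 1).
#' @param min_window Smallest R/S window length.
#' @param power_mode `"fluctuation"` or `"raw"`; see [average_power()].
#' @return A tibble with one row per cell: `cell_id`, `n_frames`,
#'   `duration_hours`, `baseline`, one `spikes_<m>x` column per threshold
#'   multiplier, `average_power`, `hurst`, `entropy`, `notes`.
#' @export
compute_cell_metrics <- function(detrended, thresholds = spike_thresholds(),
                                 n_states = 4, order = 1, min_window = 16,
                                 power_mode = c("fluctuation", "raw")) {
  power_mode <- match.arg(power_mode)
  stopifnot(all(c("cell_id", "frame", "value", "frame_interval") %in% names(detrended)))
  detrended |>
    dplyr::arrange(.data$frame) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(tr, key) {
      cell_metrics_row(tr$value, tr$frame_interval[1], thresholds,
                       n_states, order, min_window, power_mode)
    }) |>
    dplyr::ungroup()
}

cell_metrics_row <- function(values, frame_interval, thresholds,
                             n_states, order, min_window, power_mode) {
  notes <- character()
  grab <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, paste0(what, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  spikes <- tryCatch(count_spikes(values, frame_interval, thresholds),
                     error = function(e) {
                       notes <<- c(notes, paste0("spikes: ", conditionMessage(e)))
                       NULL
                     })
  spike_cols <- setNames(
    as.list(if (is.null(spikes)) rep(NA_real_, length(thresholds$multipliers))
            else spikes$spikes_per_hour),
    spike_col_names(thresholds$multipliers)
  )
  out <- tibble(
    n_frames = length(values),
    duration_hours = length(values) * frame_interval / 3600,
    baseline = mean(values),
    !!!spike_cols,
    average_power = grab("power", average_power(values, mode = power_mode)),
    hurst = grab("hurst", if (sd(values) == 0) abort("zero variance")
                 else hurst_rs(values, min_window = min_window)),
    entropy = grab("entropy", markovian_entropy(values, n_states = n_states, order = order))
  )
  out$notes <- if (length(notes)) paste(notes, collapse = "; ") else NA_character_
  out
}

spike_col_names <- function(multipliers) {
  sprintf("spikes_%sx", format(multipliers, trim = TRUE, drop0trailing = TRUE))
}

#' Names of the metric columns in a cell-metrics table
#'
#' Helper for downstream comparison designs: the spike-rate columns for the
#' given thresholds plus `average_power`, `hurst`, `entropy`.
#'
#' @param thresholds A [spike_thresholds()] object.
#' @return Character vector of column names.
#' @export
metric_column_names <- function(thresholds = spike_thresholds()) {
  c(spike_col_names(thresholds$multipliers), "average_power", "hurst", "entropy")
}
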