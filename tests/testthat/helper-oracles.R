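# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive and separate from the package implementations they check.

# Run-length spike scanner: walk the trace frame by frame and count maximal
# runs of >= min_dur consecutive frames at or above m * mean(values).
oracle_spike_count <- function(values, m, min_dur = 2) {
  thr <- m * mean(values)
  count <- 0
  run <- 0
  for (v in values) {
    if (v >= thr) {
      run <- run + 1
    } else {
      if (run >= min_dur) count <- count + 1
      run <- 0
    }
  }
  if (run >= min_dur) count <- count + 1
  count
}

# Dictionary-of-transitions Markovian entropy: string keys for k-histories.
oracle_markov_entropy <- function(values, n_states = 4, order = 1) {
  probs <- seq_len(n_states - 1) / n_states
  edges <- unique(as.numeric(quantile(values, probs = probs, names = FALSE)))
  s <- findInterval(values, edges, left.open = TRUE) + 1L
  trans <- new.env()
  n <- length(s)
  for (i in seq_len(n - order)) {
    key <- paste(s[i:(i + order - 1)], collapse = "-")
    nxt <- as.character(s[i + order])
    row <- if (!is.null(trans[[key]])) trans[[key]] else integer()
    row[nxt] <- if (!is.na(row[nxt]) && length(row[nxt])) row[nxt] + 1L else 1L
    row[is.na(row)] <- 0L
    trans[[key]] <- row
  }
  total <- 0
  for (key in ls(trans)) {
    row <- trans[[key]]
    p <- row[row > 0] / sum(row)
    total <- total - sum(p * log2(p))
  }
  total / (n_states^order * log2(n_states))
}

# Brute-force two-sample ECDF sup-difference.
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

# Long trace tibble from a named list of value vectors (valid unless NA).
make_trace_tbl <- function(values_by_cell, frame_interval = 8) {
  purrr::map_dfr(names(values_by_cell), function(id) {
    v <- values_by_cell[[id]]
    tibble::tibble(cell_id = id, frame = seq_along(v) - 1L, value = v,
                   valid = !is.na(v), frame_interval = frame_interval)
  })
}

# Detrended-layout tibble straight from values (no detrending), for metric
# tests that do not involve drift.
make_detrended_tbl <- function(values_by_cell, frame_interval = 8) {
  tb <- make_trace_tbl(values_by_cell, frame_interval)
  tb$baseline <- 0
  tb$raw <- tb$value
  tb$converged <- TRUE
  tb$valid <- NULL
  tb
}

# The two synthetic study populations used throughout: high-rate/low-amplitude
# "progenitor-like" cells and low-rate/high-amplitude "differentiated-like"
# cells.
progenitor_spec <- function(n_cells = 25, seed = 101) {
  caflux::synthetic_spec(
    n_cells = n_cells, spike_rate_per_hour = 10,
    spike_amplitude = c(1.25, 2.5), spike_duration_frames = c(2, 3),
    hurst_index = 0.5, seed = seed
  )
}

differentiated_spec <- function(n_cells = 25, seed = 202) {
  caflux::synthetic_spec(
    n_cells = n_cells, spike_rate_per_hour = 3,
    spike_amplitude = c(2, 8), spike_duration_frames = c(3, 6),
    hurst_index = 0.8, seed = seed
  )
}
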