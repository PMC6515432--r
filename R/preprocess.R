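# Track-contiguity filtering and asymmetric-least-squares (AsLS) detrending.
# Detrending runs after truncation to the longest contiguous tracked window.

#' Filter cell tracks by contiguous coverage
#'
#' A cell enters the analysis only if it was tracked in a minimum number of
#' consecutive frames (default 600 frames = 45 min at 8 s/frame). Kept traces
#' are truncated to their longest contiguous valid run (earliest run on ties);
#' shorter runs are discarded rather than bridged, because interpolation would
#' fabricate dynamics that the Hurst and entropy metrics are sensitive to.
#'
#' @param traces Long trace tibble from [read_trace_table()] or
#'   [generate_population()]: columns `cell_id`, `frame`, `value`, `valid`,
#'   `frame_interval`.
#' @param min_frames Minimum contiguous run length; default 600.
#' @return A list with `kept` (trace tibble truncated to each cell's longest
#'   run, all `valid` true) and `dropped` (tibble of `cell_id`, `longest_run`,
#'   `reason`).
#' @export
filter_contiguous_tracks <- function(traces, min_frames = 600) {
  stopifnot(min_frames >= 2)
  if (nrow(traces) == 0) {
    return(list(kept = traces, dropped = tibble(cell_id = character(),
                                                longest_run = integer(),
                                                reason = character())))
  }
  check_trace_cols(traces)
  pieces <- traces |>
    dplyr::arrange(.data$frame) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split()
  kept <- list(); dropped <- list()
  for (tr in pieces) {
    run <- longest_true_run(tr$valid)
    if (run$length >= min_frames) {
      kept[[length(kept) + 1]] <- tr[run$start:(run$start + run$length - 1), ]
    } else {
      dropped[[length(dropped) + 1]] <- tibble(
        cell_id = tr$cell_id[1],
        longest_run = run$length,
        reason = sprintf("longest contiguous run %d < %d frames", run$length, min_frames)
      )
    }
  }
  list(
    kept = if (length(kept)) dplyr::bind_rows(kept) else traces[0, ],
    dropped = if (length(dropped)) dplyr::bind_rows(dropped)
              else tibble(cell_id = character(), longest_run = integer(), reason = character())
  )
}

# Longest run of TRUE; earliest wins ties. Returns start index and length.
longest_true_run <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  is_true <- r$values & !is.na(r$values)
  if (!any(is_true)) return(list(start = 1L, length = 0L))
  lens <- ifelse(is_true, r$lengths, 0L)
  i <- which.max(lens)  # first maximum = earliest run
  list(start = starts[i], length = r$lengths[i])
}

#' Asymmetric least-squares baseline of a numeric series
#'
#' Estimates a slow-varying baseline b minimizing
#' \deqn{\sum_i w_i (y_i - b_i)^2 + \lambda \sum_i (\Delta^2 b_i)^2}
#' with asymmetric weights `w_i = p` where `y_i > b_i` and `1 - p` otherwise
#' (Whittaker smoother with second-order difference penalty). Small `p` makes
#' the baseline hug the signal from below, so slow drift is captured while
#' brief positive transients (calcium spikes) are left in the residual.
#'
#' @param y Numeric series, all finite, length >= 10.
#' @param smoothness Penalty weight lambda; default 1e5 suits slow drifts over
#'   ~900-frame recordings.
#' @param asymmetry Weight p in (0, 1); default 0.01.
#' @param max_iter Weight-update iterations; default 10.
#' @return A list: `baseline` (numeric), `iterations`, `converged` (logical;
#'   `FALSE` means the last iterate was returned after `max_iter` updates,
#'   with a warning, never an error).
#' @export
asls_baseline <- function(y, smoothness = 1e5, asymmetry = 0.01, max_iter = 10) {
  n <- length(y)
  stopifnot(n >= 10, all(is.finite(y)), smoothness > 0,
            asymmetry > 0, asymmetry < 1, max_iter >= 1)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)))
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, n)
  b_prev <- y
  b <- y
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    A <- Matrix::Diagonal(n, x = w) + P
    b <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > b, asymmetry, 1 - asymmetry)
    # fixed point: weights stable, or the baseline itself has stopped moving
    if (it > 1 &&
        (identical(w_new, w) ||
         sqrt(mean((b - b_prev)^2)) <= 1e-10 * (sqrt(mean(b^2)) + 1e-12))) {
      converged <- TRUE
      break
    }
    b_prev <- b
    w <- w_new
  }
  if (!converged) {
    warn(sprintf("AsLS weights not converged after %d iterations; returning last iterate", it))
  }
  list(baseline = b, iterations = it, converged = converged)
}

#' Detrend fluorescence traces by AsLS baseline correction
#'
#' Removes slow multiplicative drift from each cell's trace: the AsLS baseline
#' b is estimated per cell and the corrected series is `y - b + mean(b)`, so
#' the trace keeps its mean intensity level exactly (mean-preserving additive
#' correction) and percent-of-baseline spike thresholds stay interpretable on
#' the original intensity scale.
#'
#' @param traces Contiguous trace tibble (the `kept` element of
#'   [filter_contiguous_tracks()]); every row must be `valid`.
#' @inheritParams asls_baseline
#' @return A tibble with columns `cell_id`, `frame`, `value` (corrected),
#'   `baseline` (AsLS estimate), `raw`, `frame_interval`, `converged`.
#' @export
detrend_asls <- function(traces, smoothness = 1e5, asymmetry = 0.01, max_iter = 10) {
  check_trace_cols(traces)
  if (any(!traces$valid)) {
    abort("detrend_asls expects contiguous traces; run filter_contiguous_tracks first")
  }
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(tr, key) {
      fit <- asls_baseline(tr$value, smoothness = smoothness,
                           asymmetry = asymmetry, max_iter = max_iter)
      tibble(
        frame = tr$frame,
        value = tr$value - fit$baseline + mean(fit$baseline),
        baseline = fit$baseline,
        raw = tr$value,
        frame_interval = tr$frame_interval,
        converged = fit$converged
      )
    }) |>
    dplyr::ungroup()
}

check_trace_cols <- function(traces) {
  need <- c("cell_id", "frame", "value", "valid", "frame_interval")
  missing <- setdiff(need, names(traces))
  if (length(missing) > 0) {
    abort(paste0("trace table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(traces)
}
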