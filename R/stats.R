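# Group comparisons (Bonferroni-corrected two-sample K-S test gated on
# Cohen's d), expression-level correlation (Pearson + penalized-spline R^2),
# the Kruskal-Wallis stage comparison, and the two randomization controls.

#' Cohen's d (pooled standard deviation)
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled SD weighted by (n_a - 1, n_b - 1). Signed: positive when group a has
#' the larger mean. With zero pooled SD, returns `Inf`/`-Inf` for unequal
#' means and 0 for equal means.
#'
#' @param a,b Numeric samples.
#' @return Scalar d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / sqrt(sp2)
}

#' Compare two metric samples (K-S test gated on effect size)
#'
#' Two-sample Kolmogorov-Smirnov test with Bonferroni correction for the
#' family of simultaneous tests, paired with Cohen's d. The comparison is
#' declared significant only under the joint rule: adjusted p < `alpha` and
#' |d| > `d_min`. The K-S p-value is asymptotic; a warning is raised below
#' n = 20 per group.
#'
#' @param sample_a,sample_b Numeric metric values (n >= 5 each).
#' @param family_size Number of simultaneous tests in the family (>= 1);
#'   `p_adjusted = min(1, p_raw * family_size)`.
#' @param metric_name,group_a_label,group_b_label Labels carried into the
#'   result row.
#' @param alpha Significance level on the adjusted p; default 0.05.
#' @param d_min Minimum |Cohen's d|; default 0.2.
#' @return A one-row tibble: `metric_name`, `group_a_label`, `group_b_label`,
#'   `n_a`, `n_b`, `ks_statistic`, `p_raw`, `p_adjusted`, `cohens_d`,
#'   `significant`, `family_size`, `note`. With zero pooled SD and unequal
#'   means, d is infinite, significance is decided by p alone, and the row is
#'   flagged in `note`.
#' @export
compare_groups <- function(sample_a, sample_b, family_size = 1,
                           metric_name = NA_character_,
                           group_a_label = "a", group_b_label = "b",
                           alpha = 0.05, d_min = 0.2) {
  stopifnot(length(sample_a) >= 5, length(sample_b) >= 5, family_size >= 1)
  if (length(sample_a) < 20 || length(sample_b) < 20) {
    warn("asymptotic K-S p-value with a group below n = 20")
  }
  ks <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  p_raw <- unname(ks$p.value)
  p_adj <- min(1, p_raw * family_size)
  d <- cohens_d(sample_a, sample_b)
  note <- NA_character_
  if (is.infinite(d)) {
    significant <- p_adj < alpha
    note <- "zero pooled SD with unequal means; significance decided by p only"
  } else {
    significant <- (p_adj < alpha) && (abs(d) > d_min)
  }
  tibble(
    metric_name = metric_name,
    group_a_label = group_a_label, group_b_label = group_b_label,
    n_a = length(sample_a), n_b = length(sample_b),
    ks_statistic = unname(ks$statistic),
    p_raw = p_raw, p_adjusted = p_adj,
    cohens_d = d, significant = significant,
    family_size = as.integer(family_size), note = note
  )
}

#' Correlate marker expression level with a calcium metric
#'
#' Linear association as Pearson's r and nonlinear association as the R^2 of
#' a univariate penalized-spline fit (generalized additive model, smoothing
#' selected by generalized cross-validation) of the metric on the FISH score,
#' `R^2 = 1 - RSS/TSS`.
#'
#' @param joined Joined phenotype table from [join_phenotype()] (or any data
#'   frame with a `fish_score` column and the metric column).
#' @param metric_name Name of the metric column.
#' @param score_col Name of the expression-score column; default
#'   `"fish_score"`.
#' @return An object of class `ca_correlation` with fields `metric_name`,
#'   `pearson_r`, `gam_r2`, `n` and the underlying `mgcv::gam` fit; see
#'   [tidy.ca_correlation()] and [glance.ca_correlation()].
#' @export
correlate_expression <- function(joined, metric_name, score_col = "fish_score") {
  stopifnot(metric_name %in% names(joined), score_col %in% names(joined))
  x <- joined[[score_col]]
  y <- joined[[metric_name]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) abort("need >= 10 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in score or metric")
  r <- cor(x, y)
  k <- max(3, min(10, length(unique(x)) - 1))
  fit <- mgcv::gam(y ~ s(x, k = k), method = "GCV.Cp")
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(metric_name = metric_name, pearson_r = r,
                 gam_r2 = max(0, 1 - rss / tss), n = length(x), fit = fit),
            class = "ca_correlation")
}

#' @export
print.ca_correlation <- function(x, ...) {
  cat(sprintf("<ca_correlation> %s vs FISH score: n = %d, Pearson r = %.3f, GAM R2 = %.3f\n",
              x$metric_name, x$n, x$pearson_r, x$gam_r2))
  invisible(x)
}

#' Tidy an expression-correlation result
#'
#' @param x A `ca_correlation` object.
#' @param ... Unused.
#' @return One-row tibble with `metric_name`, `pearson_r`, `gam_r2`, `n`.
#' @export
tidy.ca_correlation <- function(x, ...) {
  tibble(metric_name = x$metric_name, pearson_r = x$pearson_r,
         gam_r2 = x$gam_r2, n = x$n)
}

#' @rdname tidy.ca_correlation
#' @export
glance.ca_correlation <- function(x, ...) tidy(x)

#' Run one of the population comparison designs
#'
#' Two designs over a joined phenotype table: `"pos_vs_neg"` compares
#' marker-positive cells (FISH score >= `expression_threshold`) against
#' marker-negative cells; `"posA_vs_posB"` compares cells positive for marker
#' A against cells positive for marker B (requires a `marker` column naming
#' each cell's probed marker). Every metric listed is tested; the Bonferroni
#' family is the full set of comparisons launched by the invocation, and
#' `family_size` is recorded in every row. Groups with fewer than
#' `min_group` cells yield an `"underpowered"` row with NA statistics rather
#' than being silently skipped.
#'
#' @param joined Joined phenotype table ([join_phenotype()]).
#' @param design `"pos_vs_neg"` or `"posA_vs_posB"`.
#' @param markers For `"pos_vs_neg"`, one marker name (label only); for
#'   `"posA_vs_posB"`, the two marker names matched against the `marker`
#'   column.
#' @param expression_threshold FISH-score multiplier defining positivity;
#'   default 2 (200% of background).
#' @param metrics Metric column names to compare; default
#'   [metric_column_names()] intersected with the table's columns.
#' @param alpha,d_min Joint-rule parameters (defaults 0.05, 0.2).
#' @param min_group Minimum group size; default 5.
#' @return A tibble of class `ca_comparisons`, one row per metric, in the
#'   [compare_groups()] column layout.
#' @export
run_comparison_design <- function(joined,
                                  design = c("pos_vs_neg", "posA_vs_posB"),
                                  markers,
                                  expression_threshold = 2,
                                  metrics = NULL,
                                  alpha = 0.05, d_min = 0.2, min_group = 5) {
  design <- match.arg(design)
  stopifnot("fish_score" %in% names(joined))
  if (is.null(metrics)) {
    metrics <- intersect(metric_column_names(), names(joined))
  }
  if (length(metrics) == 0) abort("no metric columns found to compare")
  positive <- joined$fish_score >= expression_threshold
  if (design == "pos_vs_neg") {
    stopifnot(length(markers) == 1)
    idx_a <- positive
    idx_b <- !positive
    lab_a <- paste0(markers, "+"); lab_b <- paste0(markers, "-")
  } else {
    stopifnot(length(markers) == 2, "marker" %in% names(joined))
    idx_a <- positive & joined$marker == markers[1]
    idx_b <- positive & joined$marker == markers[2]
    lab_a <- paste0(markers[1], "+"); lab_b <- paste0(markers[2], "+")
  }
  if (!any(idx_a) || !any(idx_b)) abort("a comparison group is empty after thresholding")
  family_size <- length(metrics)
  out <- purrr::map_dfr(metrics, function(m) {
    a <- joined[[m]][idx_a]; b <- joined[[m]][idx_b]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < min_group || length(b) < min_group) {
      return(tibble(
        metric_name = m, group_a_label = lab_a, group_b_label = lab_b,
        n_a = length(a), n_b = length(b),
        ks_statistic = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
        cohens_d = NA_real_, significant = NA,
        family_size = as.integer(family_size),
        note = sprintf("underpowered: group below %d cells", min_group)
      ))
    }
    suppressWarnings(
      compare_groups(a, b, family_size = family_size, metric_name = m,
                     group_a_label = lab_a, group_b_label = lab_b,
                     alpha = alpha, d_min = d_min)
    )
  })
  class(out) <- c("ca_comparisons", class(out))
  out
}

#' Shuffle randomization control for Hurst and entropy
#'
#' Long-range memory and Markov structure live in the sequential order of a
#' trace, so resampling the values destroys them: shuffled traces should score
#' a Markovian entropy near 1 and an R/S Hurst estimate near 0.5 regardless of
#' the original dynamics. Each trace is resampled to its own length (with
#' replacement by default; a permutation mode is available) `n_seeds` times;
#' both metrics are computed on every shuffle.
#'
#' @param detrended Detrended trace tibble ([detrend_asls()]), or any trace
#'   tibble with `cell_id`, `frame`, `value`.
#' @param n_seeds Shuffles per trace; default 1.
#' @param seed Integer seed for the whole control.
#' @param replace Sample with replacement (default `TRUE`); `FALSE` permutes.
#' @param n_states,order,min_window Metric parameters.
#' @return A list of class `ca_shuffle_control`: `samples` (tibble of
#'   `cell_id`, `shuffle`, `hurst`, `entropy`) and `summary` (one row per
#'   metric with `mean`, `sd_cells` — the SD across per-cell means — and
#'   `sd_seeds`, the mean across cells of the between-shuffle SD, `NA` when
#'   `n_seeds` = 1).
#' @export
shuffle_control <- function(detrended, n_seeds = 1, seed = 1, replace = TRUE,
                            n_states = 4, order = 1, min_window = 16) {
  stopifnot(n_seeds >= 1)
  cells <- detrended |>
    dplyr::arrange(.data$frame) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split()
  samples <- withr::with_seed(seed, {
    purrr::map_dfr(cells, function(tr) {
      purrr::map_dfr(seq_len(n_seeds), function(s) {
        v <- sample(tr$value, length(tr$value), replace = replace)
        tibble(
          cell_id = tr$cell_id[1], shuffle = s,
          hurst = tryCatch(hurst_rs(v, min_window = min_window),
                           error = function(e) NA_real_),
          entropy = markovian_entropy(v, n_states = n_states, order = order)
        )
      })
    })
  })
  per_cell <- samples |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(hurst_sd = if (n_seeds > 1) sd(.data$hurst) else NA_real_,
                     entropy_sd = if (n_seeds > 1) sd(.data$entropy) else NA_real_,
                     hurst = mean(.data$hurst, na.rm = TRUE),
                     entropy = mean(.data$entropy),
                     .groups = "drop")
  summary <- tibble(
    metric = c("hurst", "entropy"),
    mean = c(mean(per_cell$hurst, na.rm = TRUE), mean(per_cell$entropy)),
    sd_cells = c(sd(per_cell$hurst, na.rm = TRUE), sd(per_cell$entropy)),
    sd_seeds = if (n_seeds > 1) {
      c(mean(per_cell$hurst_sd, na.rm = TRUE), mean(per_cell$entropy_sd, na.rm = TRUE))
    } else c(NA_real_, NA_real_)
  )
  structure(list(samples = samples, summary = summary,
                 n_seeds = n_seeds, seed = seed, replace = replace),
            class = "ca_shuffle_control")
}

#' @export
print.ca_shuffle_control <- function(x, ...) {
  cat(sprintf("<ca_shuffle_control> %d cell(s), %d shuffle(s), %s replacement\n",
              length(unique(x$samples$cell_id)), x$n_seeds,
              if (x$replace) "with" else "without"))
  print(x$summary)
  invisible(x)
}

#' @rdname shuffle_control
#' @param x A `ca_shuffle_control` object.
#' @param ... Unused.
#' @export
tidy.ca_shuffle_control <- function(x, ...) x$samples

#' @rdname shuffle_control
#' @export
glance.ca_shuffle_control <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd_cells", "sd_seeds"))
}

#' FISH-label randomization control
#'
#' Pools the cells of two marker experiments, sorts them by FISH score, splits
#' the sorted pool into two halves (sizes may differ by one), and reruns every
#' metric comparison between the halves. On data where activity is unrelated
#' to the pooled-score split, no comparison should reach the joint
#' significance rule.
#'
#' @param joined_a,joined_b Joined phenotype tables for the two markers.
#' @param seed Seed used to break FISH-score ties randomly.
#' @param metrics,alpha,d_min,min_group As in [run_comparison_design()].
#' @return A `ca_comparisons` tibble, one row per metric.
#' @export
label_randomization_control <- function(joined_a, joined_b, seed = 1,
                                        metrics = NULL,
                                        alpha = 0.05, d_min = 0.2, min_group = 5) {
  stopifnot(nrow(joined_a) > 0, nrow(joined_b) > 0)
  shared <- intersect(names(joined_a), names(joined_b))
  pool <- dplyr::bind_rows(joined_a[shared], joined_b[shared])
  if (is.null(metrics)) metrics <- intersect(metric_column_names(), names(pool))
  ord <- withr::with_seed(seed,
    order(pool$fish_score, sample.int(nrow(pool)))
  )
  pool <- pool[ord, ]
  n <- nrow(pool)
  half <- n %/% 2
  grp_low <- pool[seq_len(half), ]
  grp_high <- pool[(half + 1):n, ]
  family_size <- length(metrics)
  out <- purrr::map_dfr(metrics, function(m) {
    a <- grp_low[[m]]; b <- grp_high[[m]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < min_group || length(b) < min_group) {
      return(tibble(metric_name = m, group_a_label = "pooled-low",
                    group_b_label = "pooled-high",
                    n_a = length(a), n_b = length(b),
                    ks_statistic = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
                    cohens_d = NA_real_, significant = NA,
                    family_size = as.integer(family_size),
                    note = sprintf("underpowered: group below %d cells", min_group)))
    }
    suppressWarnings(
      compare_groups(a, b, family_size = family_size, metric_name = m,
                     group_a_label = "pooled-low", group_b_label = "pooled-high",
                     alpha = alpha, d_min = d_min)
    )
  })
  class(out) <- c("ca_comparisons", class(out))
  out
}

#' Kruskal-Wallis test of expression fractions across stages
#'
#' Rank test of whether per-plate positive-cell percentages differ across
#' developmental stage groups.
#'
#' @param fractions Data frame of per-plate observations.
#' @param value_col Column of percentages (or any numeric response); default
#'   `"percent_positive"`.
#' @param group_col Stage label column; default `"stage"`.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`. When
#'   every observation is identical the test is degenerate and reported as
#'   H = 0, p = 1.
#' @export
kruskal_wallis_expression <- function(fractions, value_col = "percent_positive",
                                      group_col = "stage") {
  stopifnot(value_col %in% names(fractions), group_col %in% names(fractions))
  v <- fractions[[value_col]]
  g <- factor(fractions[[group_col]])
  if (nlevels(g) < 2) abort("need >= 2 stage groups")
  if (any(table(g) < 3)) abort("each stage group needs >= 3 observations")
  if (length(unique(v)) == 1) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                  n_groups = nlevels(g)))
  }
  kt <- kruskal.test(v, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = unname(kt$p.value), n_groups = nlevels(g))
}
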