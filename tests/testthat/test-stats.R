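test_that("identical samples give D = 0, d = 0, not significant", {
  set.seed(51)
  a <- rnorm(50)
  res <- compare_groups(a, a)
  expect_equal(res$ks_statistic, 0, tolerance = 1e-12)
  expect_equal(res$cohens_d, 0)
  expect_false(res$significant)
})

test_that("a unit-shift effect is detected with d near 1", {
  set.seed(52)
  ds <- replicate(20, {
    a <- rnorm(100, 1); b <- rnorm(100, 0)
    res <- compare_groups(a, b, family_size = 1)
    expect_true(res$significant)
    res$cohens_d
  })
  expect_equal(mean(ds), 1, tolerance = 0.2)
})

test_that("Bonferroni arithmetic and the joint rule hold on every row", {
  set.seed(53)
  for (i in 1:30) {
    a <- rnorm(40, sample(c(0, 0.5), 1)); b <- rnorm(40)
    fam <- sample(1:12, 1)
    res <- compare_groups(a, b, family_size = fam)
    expect_equal(res$p_adjusted, min(1, res$p_raw * fam))
    expect_identical(res$significant,
                     res$p_adjusted < 0.05 && abs(res$cohens_d) > 0.2)
  }
})

test_that("K-S statistic equals the brute-force ECDF sup-difference", {
  set.seed(54)
  for (i in 1:200) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    res <- suppressWarnings(compare_groups(a, b))
    expect_equal(res$ks_statistic, oracle_ks_stat(a, b), tolerance = 1e-12)
  }
})

test_that("Cohen's d is antisymmetric and the K-S p symmetric under group swap", {
  set.seed(55)
  a <- rnorm(30, 0.4); b <- rnorm(25)
  r1 <- compare_groups(a, b); r2 <- compare_groups(b, a)
  expect_equal(r1$cohens_d, -r2$cohens_d)
  expect_equal(r1$p_raw, r2$p_raw)
  expect_equal(r1$ks_statistic, r2$ks_statistic)
})

test_that("zero pooled SD with unequal means is flagged and decided by p", {
  res <- suppressWarnings(compare_groups(rep(1, 10), rep(2, 10)))
  expect_true(is.infinite(res$cohens_d))
  expect_match(res$note, "zero pooled SD")
  expect_identical(res$significant, res$p_adjusted < 0.05)
})

test_that("expression correlation separates linear and nonlinear association", {
  set.seed(56)
  x <- runif(200, 0.5, 5)
  # metric equal to the score: both statistics saturate
  ident <- correlate_expression(tibble::tibble(fish_score = x, m = x), "m")
  expect_equal(ident$pearson_r, 1, tolerance = 1e-6)
  expect_equal(ident$gam_r2, 1, tolerance = 1e-6)
  # independent metric: both stay near zero
  indep <- correlate_expression(tibble::tibble(fish_score = x, m = rnorm(200)), "m")
  expect_lt(abs(indep$pearson_r), 0.2)
  expect_lt(indep$gam_r2, 0.1)
  # symmetric quadratic: invisible to Pearson, captured by the smooth
  xs <- seq(-1, 1, length.out = 200) + 3
  quad <- correlate_expression(
    tibble::tibble(fish_score = xs, m = (xs - mean(xs))^2 + rnorm(200, 0, 0.05)), "m")
  expect_lt(abs(quad$pearson_r), 0.15)
  expect_gt(quad$gam_r2, 0.5)
  # tidy/glance expose the summary row
  td <- tidy(quad)
  expect_equal(td$n, 200)
  expect_equal(glance(quad)$gam_r2, quad$gam_r2)
})

test_that("correlation preconditions are enforced", {
  expect_error(correlate_expression(tibble::tibble(fish_score = 1:5, m = 1:5), "m"),
               ">= 10")
  expect_error(correlate_expression(tibble::tibble(fish_score = rep(1, 20),
                                                   m = rnorm(20)), "m"),
               "zero variance")
})

test_that("run_comparison_design tests every metric with a shared family size", {
  set.seed(57)
  n <- 40
  joined <- tibble::tibble(
    cell_id = paste0("c", 1:n),
    marker = rep(c("A", "B"), each = n / 2),
    fish_score = runif(n, 2.5, 4),
    spikes_1.25x = c(rnorm(n / 2, 30, 3), rnorm(n / 2, 10, 3)),
    hurst = rnorm(n, 0.5, 0.05),
    entropy = runif(n, 0.8, 1)
  )
  res <- run_comparison_design(joined, "posA_vs_posB", markers = c("A", "B"),
                               metrics = c("spikes_1.25x", "hurst", "entropy"))
  expect_s3_class(res, "ca_comparisons")
  expect_equal(nrow(res), 3)
  expect_true(all(res$family_size == 3))
  big <- res[res$metric_name == "spikes_1.25x", ]
  expect_true(big$significant)
  expect_gt(big$cohens_d, 0)
})

test_that("small groups are reported as underpowered, not skipped", {
  joined <- tibble::tibble(
    cell_id = paste0("c", 1:20),
    fish_score = c(rep(3, 3), rep(1, 17)),  # only 3 positive cells
    hurst = rnorm(20, 0.5, 0.02)
  )
  res <- run_comparison_design(joined, "pos_vs_neg", markers = "gad1.1",
                               metrics = "hurst")
  expect_equal(nrow(res), 1)
  expect_match(res$note, "underpowered")
  expect_true(is.na(res$significant))
})

test_that("shuffle control drives entropy toward 1 and Hurst toward 0.5", {
  set.seed(58)
  t <- seq_len(900)
  structured <- lapply(1:10, function(i)
    100 * (1 + 0.3 * sin(2 * pi * t / 80)) + rnorm(900))
  names(structured) <- paste0("c", 1:10)
  tb <- make_detrended_tbl(structured)
  orig <- compute_cell_metrics(tb)
  ctl <- shuffle_control(tb, seed = 99)
  s <- ctl$summary
  expect_gt(s$mean[s$metric == "entropy"], mean(orig$entropy))
  expect_gt(s$mean[s$metric == "entropy"], 0.98)
  expect_equal(s$mean[s$metric == "hurst"], 0.5, tolerance = 0.1)
  # single-shuffle runs report the between-seed SD as unavailable, not zero
  expect_true(all(is.na(s$sd_seeds)))
  multi <- shuffle_control(tb[tb$cell_id %in% c("c1", "c2"), ], n_seeds = 3, seed = 99)
  expect_true(all(is.finite(multi$summary$sd_seeds)))
  # identical seed reproduces identical samples
  again <- shuffle_control(tb, seed = 99)
  expect_equal(tidy(again), tidy(ctl))
})

test_that("shuffling a constant trace leaves zero entropy", {
  tb <- make_detrended_tbl(list(c1 = rep(100, 900)))
  ctl <- shuffle_control(tb, seed = 1)
  expect_equal(ctl$samples$entropy, 0)
})

test_that("label randomization splits the pooled score ranking into halves", {
  set.seed(59)
  mk_joined <- function(n, label) tibble::tibble(
    cell_id = paste0(label, 1:n),
    fish_score = runif(n, 0.5, 4),
    hurst = rnorm(n, 0.5, 0.05),
    entropy = runif(n, 0.9, 1)
  )
  # odd pooled count: group sizes differ by one
  res <- label_randomization_control(mk_joined(13, "a"), mk_joined(12, "b"),
                                     metrics = c("hurst", "entropy"))
  expect_equal(sort(unique(res$n_a + res$n_b)), 25)
  expect_true(all(abs(res$n_a - res$n_b) <= 1))
  # exchangeable activity: no significant comparison expected
  res2 <- label_randomization_control(mk_joined(60, "a"), mk_joined(60, "b"),
                                      metrics = c("hurst", "entropy"))
  expect_false(any(res2$significant))
})

test_that("Kruskal-Wallis on stage fractions behaves across designs", {
  set.seed(60)
  # identical distributions: large p
  same <- tibble::tibble(stage = rep(c("St14", "St18", "St22"), each = 12),
                         percent_positive = rnorm(36, 50, 5))
  expect_gt(kruskal_wallis_expression(same)$p_value, 0.05)
  # one stage shifted by 30 points: detected
  shift <- same
  shift$percent_positive[shift$stage == "St22"] <-
    shift$percent_positive[shift$stage == "St22"] + 30
  expect_lt(kruskal_wallis_expression(shift)$p_value, 0.05)
  # two groups reduce to a rank test with H >= 0
  two <- tibble::tibble(stage = rep(c("a", "b"), each = 5),
                        percent_positive = rnorm(10, 50, 5))
  expect_gte(kruskal_wallis_expression(two)$statistic, 0)
  # all-identical values: degenerate convention p = 1
  flat <- tibble::tibble(stage = rep(c("a", "b"), each = 5),
                         percent_positive = rep(40, 10))
  kt <- kruskal_wallis_expression(flat)
  expect_equal(kt$p_value, 1)
  expect_equal(kt$statistic, 0)
})
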