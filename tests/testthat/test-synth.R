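test_that("fGn generation is seeded and matches the closed-form autocorrelation", {
  x1 <- generate_fgn(1000, 0.8, seed = 5)
  x2 <- generate_fgn(1000, 0.8, seed = 5)
  expect_identical(x1, x2)
  # white-noise limit: lag-1 autocorrelation near 0
  w <- generate_fgn(10000, 0.5, seed = 6)
  expect_lt(abs(cor(w[-1], w[-10000])), 0.05)
  # persistent fGn: rho_1 = 2^(2H-1) - 1
  p <- generate_fgn(10000, 0.8, seed = 7)
  rho1 <- 2^(2 * 0.8 - 1) - 1
  expect_equal(cor(p[-1], p[-10000]), rho1, tolerance = 0.05 / rho1)
  # unit marginal variance
  expect_equal(var(p), 1, tolerance = 0.15)
})

test_that("a noiseless, spikeless, driftless spec yields a constant trace", {
  sp <- synthetic_spec(n_cells = 1, spike_rate_per_hour = 0, noise_sd = 0,
                       drift_kind = "none", seed = 1)
  tr <- generate_trace(sp, 1)
  expect_true(all(tr$trace$value == sp$baseline_level))
  expect_equal(nrow(tr$truth), 0)
})

test_that("generation is deterministic per (seed, cell_index)", {
  sp <- progenitor_spec(seed = 77)
  a <- generate_trace(sp, 3)
  b <- generate_trace(sp, 3)
  expect_identical(a$trace$value, b$trace$value)
  expect_identical(a$truth, b$truth)
  c <- generate_trace(sp, 4)
  expect_false(identical(a$trace$value, c$trace$value))
})

test_that("ground-truth spike bookkeeping matches the injected pulses", {
  sp <- synthetic_spec(n_cells = 1, spike_rate_per_hour = 6, noise_sd = 0,
                       drift_kind = "none", spike_amplitude = c(2.5, 2.5),
                       spike_duration_frames = c(3, 3), seed = 9)
  tr <- generate_trace(sp, 1)
  # every truth run sits at the plateau level in the trace
  for (i in seq_len(nrow(tr$truth))) {
    idx <- (tr$truth$onset_frame[i] + 1):(tr$truth$onset_frame[i] + tr$truth$duration_frames[i])
    expect_true(all(tr$trace$value[idx] == 250))
  }
  # frames outside truth runs are at baseline
  spike_frames <- unlist(purrr::map2(tr$truth$onset_frame + 1, tr$truth$duration_frames,
                                     function(o, d) o:(o + d - 1)))
  expect_true(all(tr$trace$value[-spike_frames] == 100))
})

test_that("count_spikes recovers the injected spike count on >=95% of cells", {
  sp <- synthetic_spec(n_cells = 200, spike_rate_per_hour = 6, noise_sd = 0.02,
                       spike_amplitude = c(2.5, 2.5), spike_duration_frames = c(3, 3),
                       seed = 123)
  hits <- vapply(seq_len(200), function(i) {
    tr <- generate_trace(sp, i)
    truth_n <- if (nrow(tr$truth) > 0) tr$truth$n_spikes_true[1] else 0L
    got <- count_spikes(tr$trace$value, sp$frame_interval)$n_spikes[3]  # 2.0x
    abs(got - truth_n) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("hurst_rs recovers the generator's Hurst index within 0.1", {
  for (H in c(0.3, 0.5, 0.8)) {
    est <- vapply(1:30, function(i) hurst_rs(generate_fgn(900, H, seed = 1000 + i)),
                  numeric(1))
    expect_equal(mean(est), H, tolerance = 0.1 / H)
  }
})

test_that("generated populations round-trip through the io and fish modules", {
  d <- withr::local_tempdir()
  sa <- progenitor_spec(n_cells = 10, seed = 31)
  sb <- differentiated_spec(n_cells = 10, seed = 32)
  pop <- generate_population(sa, sb, labels = c("sox2", "tubb2b"), out_dir = d)
  traces <- read_trace_table(pop$paths$trace)
  expect_equal(length(unique(traces$cell_id)), 20)
  expect_equal(traces$value[traces$cell_id == "sox21"],
               pop$traces$value[pop$traces$cell_id == "sox21"])
  fish <- read_fish_table(pop$paths$fish, plate_id = "plate1")
  scores <- compute_fish_scores(fish)
  map <- read_roi_map(pop$paths$roi_map)
  metrics <- tibble::tibble(cell_id = unique(traces$cell_id))
  joined <- join_phenotype(metrics, scores, map, quiet = TRUE)
  expect_equal(nrow(joined), 20)  # 1:1 over all calcium cells
})

test_that("the FISH model places positives and the background anchor where specified", {
  sa <- synthetic_spec(n_cells = 30, fish_positive_fraction = 1,
                       fish_positive_score_mean = 3, seed = 41)
  sb <- synthetic_spec(n_cells = 30, fish_positive_fraction = 1,
                       fish_positive_score_mean = 3, seed = 42)
  pop <- generate_population(sa, sb)
  scores <- compute_fish_scores(pop$fish)
  cell_scores <- scores[grepl("^f_", scores$fish_roi_id), ]
  expect_true(all(cell_scores$positive_2x))            # every cell positive at 200%
  expect_equal(mean(cell_scores$fish_score), 3, tolerance = 0.45)
  expect_equal(unique(scores$background), 10, tolerance = 1)
})
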