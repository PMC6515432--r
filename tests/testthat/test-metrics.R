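test_that("spike counting follows the >=2-frame, percent-of-mean definition", {
  # constant trace: nothing exceeds 1.25x its own mean
  const <- count_spikes(rep(100, 900), 8)
  expect_true(all(const$spikes_per_hour == 0))

  # one 3-frame plateau at 250 in a 2 h trace: one spike at 1.25/1.5/2x, none at 3x
  v <- rep(100, 900); v[101:103] <- 250
  cs <- count_spikes(v, 8)
  expect_equal(cs$spikes_per_hour[cs$multiplier %in% c(1.25, 1.5, 2)], rep(0.5, 3))
  expect_equal(cs$spikes_per_hour[cs$multiplier >= 3], rep(0, 3))

  # single-frame excursions are never spikes, however large
  v2 <- rep(100, 900); v2[500] <- 900
  expect_true(all(count_spikes(v2, 8)$n_spikes == 0))

  # runs separated by one sub-threshold frame are distinct spikes
  v3 <- rep(100, 100); v3[10:11] <- 300; v3[13:14] <- 300
  expect_equal(count_spikes(v3, 8)$n_spikes[1], 2L)
})

test_that("count_spikes agrees exactly with the brute-force run-length oracle", {
  set.seed(11)
  thr <- spike_thresholds()
  for (i in 1:300) {
    n <- sample(20:80, 1)
    v <- 100 + abs(rnorm(n, 0, 30))
    if (runif(1) < 0.5) v[sample(n, 3)] <- runif(3, 200, 900)
    cs <- count_spikes(v, 8, thr)
    for (j in seq_along(thr$multipliers)) {
      expect_identical(cs$n_spikes[j],
                       as.integer(oracle_spike_count(v, thr$multipliers[j])))
    }
  }
})

test_that("supra-threshold frame counts are monotone non-increasing in the multiplier", {
  set.seed(5)
  for (i in 1:50) {
    v <- 100 + abs(rnorm(300, 0, 50))
    cs <- count_spikes(v, 8)
    expect_true(all(diff(cs$supra_frames) <= 0))
  }
})

test_that("count_spikes rejects non-positive baselines", {
  expect_error(count_spikes(rep(0, 10), 8), "positive")
})

test_that("average power matches direct arithmetic", {
  expect_equal(average_power(rep(42, 100)), 0)
  # alternating 150/50: fluctuations +-0.5 around mean 100 -> power 0.25
  expect_equal(average_power(rep(c(150, 50), 50)), 0.25)
  # sinusoid of relative amplitude A over whole periods -> A^2/2
  A <- 0.3
  t <- seq_len(1200)
  v <- 100 * (1 + A * sin(2 * pi * t / 100))
  expect_equal(average_power(v), A^2 / 2, tolerance = 1e-3)
  # raw mode squares intensities directly
  expect_equal(average_power(c(3, 4), mode = "raw"), 12.5)
  expect_error(average_power(c(-1, 1)), "zero-mean")
})

test_that("power is non-negative and zero only for constant traces", {
  set.seed(9)
  for (i in 1:30) {
    v <- 100 + rnorm(50, 0, 10)
    expect_gt(average_power(v), 0)
  }
})

test_that("Markovian entropy matches the dictionary oracle to 1e-12", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(50:300, 1)
    v <- rnorm(n)
    if (runif(1) < 0.3) v <- round(v, 1)  # induce ties
    expect_equal(markovian_entropy(v), oracle_markov_entropy(v), tolerance = 1e-12)
  }
  # higher order
  for (i in 1:20) {
    v <- rnorm(200)
    expect_equal(markovian_entropy(v, order = 2),
                 oracle_markov_entropy(v, order = 2), tolerance = 1e-12)
  }
})

test_that("entropy edge cases: cycles and constants are fully predictable", {
  expect_equal(markovian_entropy(rep(1:4, 100)), 0)
  expect_equal(markovian_entropy(rep(7, 100)), 0)
  # i.i.d. noise at ~900 frames scores near the randomized-control value
  set.seed(21)
  e <- replicate(30, markovian_entropy(rnorm(900)))
  expect_equal(mean(e), 0.996, tolerance = 0.004)
  expect_lt(sd(e), 0.005)
})

test_that("entropy stays in [0, 1] across trace families", {
  set.seed(17)
  traces <- c(
    lapply(1:20, function(i) rnorm(sample(30:900, 1))),
    lapply(1:20, function(i) rep(sin(seq_len(60)), length.out = 300)),
    lapply(1:20, function(i) { v <- rep(100, 200); v[sample(200, 5)] <- 500; v }),
    list(rep(2, 50), rep(c(1, 2), 100))
  )
  for (v in traces) {
    e <- markovian_entropy(v)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("shuffling raises the entropy of structured traces", {
  set.seed(23)
  t <- seq_len(900)
  v <- 100 * (1 + 0.3 * sin(2 * pi * t / 90)) + rnorm(900, 0, 1)
  e0 <- markovian_entropy(v)
  expect_lt(e0, 0.9)
  shuffled <- replicate(20, markovian_entropy(sample(v, 900, replace = TRUE)))
  expect_gt(mean(shuffled), e0)
})

test_that("R/S Hurst is near 0.5 for white noise and recovers fGn memory", {
  set.seed(31)
  h_wn <- replicate(50, hurst_rs(rnorm(900)))
  expect_equal(mean(h_wn), 0.5, tolerance = 0.1)
  h_fgn <- replicate(50, hurst_rs(generate_fgn(900, 0.8)))
  expect_equal(mean(h_fgn), 0.8, tolerance = 0.1 / 0.8)
})

test_that("R/S errors on degenerate inputs", {
  expect_error(hurst_rs(rep(5, 900)), "constant")
  expect_error(hurst_rs(rnorm(40)), "window lengths")
})

test_that("compute_cell_metrics bundles all four metrics and flags failures", {
  set.seed(37)
  spiky <- rep(100, 900) + rnorm(900); spiky[50:53] <- 400
  tb <- make_detrended_tbl(list(good = spiky, flat = rep(100, 900)))
  m <- compute_cell_metrics(tb)
  good <- m[m$cell_id == "good", ]
  expect_true(all(is.finite(c(good$average_power, good$hurst, good$entropy))))
  expect_gt(good$spikes_3x, 0)
  flat <- m[m$cell_id == "flat", ]
  expect_true(all(flat[spike_col_names <- grep("^spikes_", names(m), value = TRUE)] == 0))
  expect_equal(flat$average_power, 0)
  expect_equal(flat$entropy, 0)
  expect_true(is.na(flat$hurst))
  expect_match(flat$notes, "zero variance")
  expect_equal(good$duration_hours, 2)
})
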