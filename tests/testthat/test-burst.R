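test_that("a constant firing rate is pure tonic activity", {
  mv <- toy_movie(nt = 600)
  mv$data[2, 2, ] <- 1   # 1 count every frame, zero excursion
  ph <- filter_phasic(mv)
  expect_equal(sum(ph$data), 0)
})

test_that("an isolated step burst is recovered on exactly its frames", {
  mv <- toy_movie(nt = 600)
  mv$data[2, 2, 100:110] <- 20
  ph <- filter_phasic(mv)
  expect_equal(which(ph$data[2, 2, ] == 1), 100:110)
  expect_equal(sum(ph$data), 11)
})

test_that("phasic support is a subset of raw activity support", {
  for (sd in c(41, 42)) {
    sim <- simulate_recording(simulation_params(
      nx = 8, ny = 8, duration_s = 300, wave_rate_per_min = 2,
      rng_seed = sd))
    mv <- rasterize(sim$spikes)
    ph <- filter_phasic(mv)
    expect_true(all(mv$data[ph$data == 1] > 0))
  }
})

test_that("raising the threshold never adds phasic frames", {
  sim <- simulate_recording(simulation_params(
    nx = 8, ny = 8, duration_s = 300, wave_rate_per_min = 2,
    rng_seed = 43))
  mv <- rasterize(sim$spikes)
  lo <- filter_phasic(mv, burst_params(threshold_k = 4))
  hi <- filter_phasic(mv, burst_params(threshold_k = 8))
  expect_true(all(lo$data[hi$data == 1] == 1))
  expect_lte(sum(hi$data), sum(lo$data))
})

test_that("a uniform baseline shift leaves detected bursts unchanged", {
  # deterministic elevated-tonic scenario: the rolling median and the
  # threshold translate with the added constant, so the supra-threshold
  # set is identical away from the constant's own (zero-excursion) level
  mv <- toy_movie(nt = 600)
  mv$data[2, 2, 100:110] <- 20
  mv$data[3, 3, 300:306] <- 15
  shifted <- mv
  shifted$data <- mv$data + 2   # constant 2 counts/frame everywhere
  ph0 <- filter_phasic(mv)
  ph1 <- filter_phasic(shifted)
  expect_equal(which(ph1$data[2, 2, ] == 1), which(ph0$data[2, 2, ] == 1))
  expect_equal(which(ph1$data[3, 3, ] == 1), which(ph0$data[3, 3, ] == 1))
})

test_that("a movie shorter than the baseline window is rejected", {
  mv <- toy_movie(nt = 30)
  expect_error(filter_phasic(mv, burst_params(baseline_window_s = 60)),
               "parameter error")
  expect_silent(filter_phasic(mv, burst_params(baseline_window_s = 20)))
})

test_that("burst parameter invariants are enforced", {
  expect_error(burst_params(baseline_window_s = 1, smoothing_s = 2),
               "must exceed")
  expect_error(burst_params(threshold_k = 0))
})
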