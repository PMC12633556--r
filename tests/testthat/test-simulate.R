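test_that("identical seeds reproduce the recording exactly", {
  p <- simulation_params(nx = 8, ny = 8, duration_s = 200,
                         wave_rate_per_min = 2, rng_seed = 99)
  a <- simulate_recording(p)
  b <- simulate_recording(p)
  expect_identical(a$spikes$time_s, b$spikes$time_s)
  expect_identical(a$spikes$channel, b$spikes$channel)
  expect_identical(a$truth$labels, b$truth$labels)
  c <- simulate_recording(simulation_params(nx = 8, ny = 8,
    duration_s = 200, wave_rate_per_min = 2, rng_seed = 100))
  expect_false(identical(a$spikes$time_s, c$spikes$time_s))
})

test_that("zero rates give an empty recording", {
  p <- simulation_params(duration_s = 100, wave_rate_per_min = 0,
                         tonic_rate_hz = 0, wavefront_rate_hz = 0)
  sim <- simulate_recording(p)
  expect_length(sim$spikes$time_s, 0)
  expect_equal(nrow(sim$truth$waves), 0)
  expect_true(all(sim$truth$labels == 0L))
})

test_that("a single clean planar wave is recovered exactly", {
  # place one wave deterministically: rate low enough for one draw
  p <- simulation_params(nx = 10, ny = 10, duration_s = 120,
                         wave_rate_per_min = 60 / 120,
                         tonic_rate_hz = 0, wavefront_rate_hz = 30,
                         rng_seed = 4)
  sim <- simulate_recording(p)
  expect_gte(nrow(sim$truth$waves), 1)
  det <- run_detection(sim)
  expect_equal(det$labels$n_waves, nrow(sim$truth$waves))
  # detected support equals the truth support (as sets, per wave)
  expect_equal(det$labels$labels > 0, sim$truth$labels > 0)
})

test_that("every wavefront spike lies inside its wave's true support", {
  sim <- simulate_recording(simulation_params(
    nx = 8, ny = 8, duration_s = 300, wave_rate_per_min = 2,
    tonic_rate_hz = 0, rng_seed = 6))
  mv <- rasterize(sim$spikes)
  expect_true(all(mv$data[sim$truth$labels == 0L] == 0))
  expect_equal(sum(mv$data), length(sim$spikes$time_s))
})

test_that("waves never touch under segmentation connectivity", {
  sim <- simulate_recording(simulation_params(
    nx = 10, ny = 10, duration_s = 600, wave_rate_per_min = 3,
    rng_seed = 8))
  tl <- sim$truth$labels
  expect_gte(max(tl), 2)
  # labeling the union of supports must reproduce the true partition
  lb <- segment_waves(array(as.integer(tl > 0), dim(tl)), min_pixels = 1)
  expect_equal(lb$n_waves, max(tl))
})

test_that("developmental presets are valid and ordered as expected", {
  groups <- c("0wk", "0.5wk", "1wk", "1.5wk", "2wk")
  ps <- lapply(groups, wave_preset)
  for (p in ps) expect_s3_class(p, "simulation_params")
  names(ps) <- groups
  dd <- ps[["1.5wk"]]$direction_distribution
  expect_equal(names(dd)[which.max(dd)], "N")
  expect_gt(ps[["2wk"]]$wave_rate_per_min, ps[["0.5wk"]]$wave_rate_per_min)
  expect_gt(ps[["2wk"]]$speed_um_s, ps[["0.5wk"]]$speed_um_s)
  expect_error(wave_preset("3wk"), "unknown age group")
})
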