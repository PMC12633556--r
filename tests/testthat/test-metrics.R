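planar_wave_array <- function(nx = 8, ny = 8, frames = 5, width = 1,
                              step = 1) {
  # band of `width` columns advancing `step` px per frame along +x
  arr <- array(0L, c(nx, ny, frames))
  for (f in seq_len(frames)) {
    lead <- 1 + step * (f - 1)
    cols <- intersect(seq(lead - width + 1, lead), seq_len(nx))
    if (length(cols)) arr[cols, , f] <- 1L
  }
  arr
}

test_that("wave area counts the distinct spatial footprint times pitch^2", {
  # 4 distinct xy pixels, some active in several frames
  w <- manual_wave(rbind(c(1, 1, 1), c(2, 1, 1), c(1, 1, 2), c(2, 2, 2),
                         c(1, 2, 3)), dims = c(4, 4, 4))
  expect_equal(wave_area(w), 4 * 87.5^2)
  expect_equal(wave_area(w), 30625)

  single <- manual_wave(rbind(c(2, 2, 1), c(2, 2, 2)), dims = c(4, 4, 4))
  expect_equal(wave_area(single), 7656.25)

  set.seed(13)
  for (i in 1:10) {
    co <- cbind(sample(1:6, 40, TRUE), sample(1:6, 40, TRUE),
                sample(1:5, 40, TRUE))
    co <- unique(co)
    w <- manual_wave(co, dims = c(6, 6, 5), pitch_um = 50)
    expect_equal(wave_area(w), nrow(unique(co[, 1:2])) * 50^2)
  }
})

test_that("wave duration is the frame span times the frame interval", {
  w <- manual_wave(rbind(c(1, 1, 10), c(1, 2, 10), c(2, 2, 25)),
                   dims = c(4, 4, 30))
  expect_equal(wave_duration(w), 15)
  expect_equal(wave_duration(w, frame_s = 2), 30)
  single <- manual_wave(rbind(c(1, 1, 3), c(2, 1, 3)), dims = c(4, 4, 5))
  expect_equal(wave_duration(single), 0)

  for (k in c(2, 5, 8)) {
    ws <- arr_waves(planar_wave_array(frames = k))
    expect_equal(wave_duration(ws[[1]]), (k - 1) * 1)
  }
})

test_that("a planar wave advancing one pixel per second moves at 87.5 um/s", {
  ws <- arr_waves(planar_wave_array(frames = 6))
  expect_equal(wave_speed(ws[[1]]), 87.5)
})

test_that("speed handles stationary, fast and irregular waves like the oracle", {
  # identical footprint every frame: no leading edge
  arr <- array(0L, c(6, 6, 4)); arr[2:3, 2:3, ] <- 1L
  ws <- arr_waves(arr)
  expect_equal(wave_speed(ws[[1]]), 0)

  # point wave hopping 2 px per frame along a line
  w2 <- manual_wave(rbind(c(1, 3, 1), c(3, 3, 2), c(5, 3, 3)),
                    dims = c(8, 8, 4))
  expect_equal(wave_speed(w2), 175)
  expect_equal(wave_speed(w2), bf_speed(w2))

  # single-frame wave has no defined speed
  w3 <- manual_wave(rbind(c(1, 1, 2), c(2, 1, 2)), dims = c(4, 4, 3))
  expect_true(is.na(wave_speed(w3)))

  set.seed(17)
  for (i in 1:8) {
    arr <- array(0L, c(10, 10, 6))
    arr[3:6, 3:6, 1] <- 1L
    for (t in 2:6) {
      prev <- arr[, , t - 1]
      grow <- which(prev == 1, arr.ind = TRUE)
      arr[, , t] <- prev
      sel <- grow[runif(nrow(grow)) < 0.4, , drop = FALSE]
      sel[, 1] <- pmin(sel[, 1] + 1, 10)
      arr[cbind(sel, t)] <- 1L
    }
    ws <- arr_waves(arr)
    expect_equal(wave_speed(ws[[1]]), bf_speed(ws[[1]]), tolerance = 1e-10)
  }
})

test_that("initiation site is the centroid of the first frame", {
  w <- manual_wave(rbind(c(3, 7, 2), c(3, 7, 3), c(4, 7, 3)),
                   dims = c(8, 8, 4))
  expect_equal(initiation_site(w), c(x = 3, y = 7))
  w2 <- manual_wave(rbind(c(1, 1, 1), c(3, 1, 1), c(2, 2, 2)),
                    dims = c(4, 4, 3))
  expect_equal(initiation_site(w2), c(x = 2, y = 1))
})

test_that("initiation bias counts nasal-half origins with ties nasal", {
  expect_equal(initiation_bias(c(6, 7, 8), optic_nerve_x = 5), 1)
  expect_equal(initiation_bias(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                               optic_nerve_x = 5.5), 0.5)
  # exactly on the split line counts nasal
  expect_equal(initiation_bias(c(5, 1), optic_nerve_x = 5), 0.5)
  expect_error(initiation_bias(numeric(0), optic_nerve_x = 5),
               "no waves")
})

test_that("flow field points along propagation and mirrors with the wave", {
  arr <- planar_wave_array(frames = 6, width = 2)
  ws <- arr_waves(arr)
  ff <- flow_field(ws[[1]])
  # interior pixels all flow in +x, none in y
  expect_true(all(ff$vx > 0))
  expect_equal(ff$vy, rep(0, nrow(ff)))

  # stationary wave: zero field
  arr2 <- array(0L, c(6, 6, 4)); arr2[2:3, 2:3, ] <- 1L
  ff2 <- flow_field(arr_waves(arr2)[[1]])
  expect_equal(ff2$vx, rep(0, nrow(ff2)))
  expect_equal(ff2$vy, rep(0, nrow(ff2)))

  # mirrored wave: vx negated, vy unchanged
  mirr <- arr[dim(arr)[1]:1, , ]
  fm <- flow_field(arr_waves(mirr)[[1]])
  expect_equal(sort(fm$vx), sort(-ff$vx))
  expect_equal(mean(fm$vy), 0)
})

test_that("direction classes split at 45-degree boundaries, ties counterclockwise", {
  mk <- function(deg) data.frame(vx = cos(deg * pi / 180),
                                 vy = sin(deg * pi / 180))
  expect_equal(propagation_direction(mk(0))$class, "N")
  expect_equal(propagation_direction(mk(44))$class, "N")
  expect_equal(propagation_direction(mk(45))$class, "D")
  expect_equal(propagation_direction(mk(46))$class, "D")
  expect_equal(propagation_direction(mk(135))$class, "T")
  expect_equal(propagation_direction(mk(180))$class, "T")
  expect_equal(propagation_direction(mk(225))$class, "V")
  expect_equal(propagation_direction(mk(270))$class, "V")
  expect_equal(propagation_direction(mk(-44))$class, "N")
  # zero mean vector is unclassified
  zero <- data.frame(vx = c(1, -1), vy = c(0, 0))
  expect_true(is.na(propagation_direction(zero)$class))
})

test_that("nasal bias index is the classified-nasal fraction", {
  cls <- rep(c("N", "T", "D", "V"), each = 10)
  expect_equal(nasal_bias(cls), 0.25)
  expect_equal(nasal_bias(rep("N", 7)), 1)
  expect_equal(nasal_bias(cls, direction = "T"), 0.25)
  expect_equal(nasal_bias(c("N", "N", "T", NA)), 2 / 3)
  expect_error(nasal_bias(c(NA_character_, NA)), "no classified waves")
})

test_that("local synchrony contrasts wavefront with ahead-of-front activity", {
  mv <- toy_movie(nx = 6, ny = 6, nt = 5)
  w <- manual_wave(rbind(c(2, 2, 1), c(3, 2, 2)), dims = c(6, 6, 5))
  # wavefront pixel (3,2) spikes at t=2; nothing ahead anywhere
  mv$data[2, 2, 1] <- 4
  mv$data[3, 2, 2] <- 6
  expect_equal(local_synchrony(w, mv), 1)
  # equal activity on a non-member pixel newly active at t=2
  mv$data[5, 2, 2] <- 6
  expect_equal(local_synchrony(w, mv), 0.5)

  single <- manual_wave(rbind(c(1, 1, 2), c(2, 1, 2)), dims = c(6, 6, 5))
  expect_error(local_synchrony(single, mv), "single-frame")
})

test_that("wave frequency follows the per-pixel unique-wave formula", {
  arr <- array(0L, c(3, 3, 600))
  arr[2, 2, 10:11] <- 1L   # wave 1 crosses the pixel
  arr[2, 2, 400:401] <- 1L # wave 2 crosses the pixel
  lb <- segment_waves(arr)
  expect_equal(lb$n_waves, 2)
  lb$valid_mask <- matrix(FALSE, 3, 3); lb$valid_mask[2, 2] <- TRUE
  f <- wave_frequency(lb, recording_s = 600)
  expect_equal(f$per_pixel_per_min, 2 / 600 * 60)
  expect_equal(f$total_per_min, 0.2)

  empty <- segment_waves(array(0L, c(3, 3, 120)))
  expect_equal(wave_frequency(empty)$per_pixel_per_min, 0)
})

test_that("inter-wave intervals pool per-pixel onset gaps in minutes", {
  arr <- array(0L, c(3, 3, 300))
  arr[2, 2, 61:62] <- 1L    # onset frame 61 -> t = 60 s
  arr[2, 2, 181:182] <- 1L  # onset frame 181 -> t = 180 s
  lb <- segment_waves(arr)
  expect_equal(inter_wave_intervals(lb), 2)

  one <- array(0L, c(3, 3, 300)); one[2, 2, 5:6] <- 1L
  expect_length(inter_wave_intervals(segment_waves(one)), 0)
})

test_that("metrics scale correctly with pitch and frame interval", {
  ws <- arr_waves(planar_wave_array(frames = 5))
  w <- ws[[1]]
  expect_equal(wave_speed(w, pitch_um = 175), 2 * wave_speed(w))
  expect_equal(wave_area(w, pitch_um = 175), 4 * wave_area(w))
  expect_equal(wave_duration(w, frame_s = 2), 2 * wave_duration(w))
  expect_equal(wave_speed(w, frame_s = 2), wave_speed(w) / 2)
})

test_that("bounded indices stay in range on simulated recordings", {
  sim <- simulate_recording(simulation_params(
    nx = 10, ny = 10, duration_s = 400, wave_rate_per_min = 2,
    ahead_noise_ratio = 0.2, rng_seed = 23))
  det <- run_detection(sim)
  tab <- wave_table(det$labels, det$movie)
  expect_true(all(tab$area_um2 >= 0))
  expect_true(all(tab$duration_s >= 0))
  expect_true(all(tab$speed_um_s >= 0, na.rm = TRUE))
  expect_true(all(tab$lsi >= 0 & tab$lsi <= 1, na.rm = TRUE))
  s <- summarize_recording(det$labels, det$movie)
  expect_gte(s$ibi, 0); expect_lte(s$ibi, 1)
  expect_gte(s$nbi, 0); expect_lte(s$nbi, 1)
  expect_true(all(inter_wave_intervals(det$labels) > 0))
})

test_that("per-pair speed averaging matches its definition", {
  w <- manual_wave(rbind(c(1, 1, 1), c(2, 1, 2), c(2, 1, 3), c(3, 1, 3),
                         c(4, 1, 3)), dims = c(6, 6, 4))
  expect_equal(wave_speed(w), mean(c(1, 1, 2)) * 87.5)
  expect_equal(wave_speed(w, per_pair = TRUE),
               mean(c(1, (1 + 2) / 2)) * 87.5)
  # uniform advance: the two readings coincide
  ws <- arr_waves(planar_wave_array(frames = 6))
  expect_equal(wave_speed(ws[[1]], per_pair = TRUE), wave_speed(ws[[1]]))
})
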