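test_that("well-separated blobs get distinct wave IDs", {
  arr <- array(0L, c(10, 10, 10))
  arr[2:3, 2:3, 2:3] <- 1L
  arr[7:8, 7:8, 7:8] <- 1L
  lb <- segment_waves(arr)
  expect_equal(lb$n_waves, 2)
  expect_setequal(unique(as.vector(lb$labels)), c(0L, 1L, 2L))
  # first-encounter order: the low-t blob is wave 1
  expect_equal(lb$labels[2, 2, 2], 1L)
})

test_that("an isolated active pixel is discarded, not counted as a wave", {
  arr <- array(0L, c(5, 5, 5))
  arr[3, 3, 3] <- 1L
  lb <- segment_waves(arr)   # default min_pixels = 2
  expect_equal(lb$n_waves, 0)
  expect_true(all(lb$labels == 0L))
})

test_that("segmentation matches the brute-force component oracle", {
  skip_if_not_installed("igraph")
  for (sd in 1:15) {
    set.seed(sd)
    arr <- array(as.integer(runif(12 * 12 * 20) < 0.05), c(12, 12, 20))
    for (conn in c("26", "6"))
      expect_identical(seg_partition(arr, conn, min_pixels = 1),
                       bf_components(arr, as.integer(conn)))
  }
})

test_that("segmentation is deterministic with contiguous first-encounter labels", {
  set.seed(77)
  arr <- array(as.integer(runif(15 * 15 * 30) < 0.08), c(15, 15, 30))
  a <- segment_waves(arr)
  b <- segment_waves(arr)
  expect_identical(a$labels, b$labels)
  if (a$n_waves > 0)
    expect_equal(sort(unique(a$labels[a$labels > 0])), seq_len(a$n_waves))
})

test_that("temporal gaps split waves and shared-frame contact merges them", {
  # same spatial footprint, active frames 2-3 and 6-7: > 1 empty frame
  arr <- array(0L, c(6, 6, 10))
  arr[2:4, 2:4, 2:3] <- 1L
  arr[2:4, 2:4, 6:7] <- 1L
  expect_equal(segment_waves(arr)$n_waves, 2)
  # touching in a shared frame merges into one wave
  arr2 <- array(0L, c(6, 6, 10))
  arr2[1:3, 1:3, 2:4] <- 1L
  arr2[3:5, 3:5, 4:6] <- 1L   # share voxel region at frame 4
  expect_equal(segment_waves(arr2)$n_waves, 1)
})

test_that("connectivity choice changes diagonal linkage", {
  arr <- array(0L, c(5, 5, 5))
  arr[2, 2, 2] <- 1L
  arr[3, 3, 3] <- 1L   # full space-time diagonal
  expect_equal(segment_waves(arr, connectivity("26"), min_pixels = 1)$n_waves, 1)
  expect_equal(segment_waves(arr, connectivity("6"), min_pixels = 1)$n_waves, 2)
})

test_that("extract_waves tiles the labeled support exactly", {
  arr <- array(0L, c(8, 8, 12))
  arr[2:4, 2:4, 4:8] <- 1L
  lb <- segment_waves(arr)
  ws <- extract_waves(lb)
  expect_length(ws, 1)
  expect_equal(ws[[1]]$t_start, 4)
  expect_equal(ws[[1]]$t_end, 8)

  set.seed(9)
  arr2 <- array(as.integer(runif(10 * 10 * 20) < 0.1), c(10, 10, 20))
  lb2 <- segment_waves(arr2)
  ws2 <- extract_waves(lb2)
  expect_equal(sum(vapply(ws2, function(w) nrow(w$coords), integer(1))),
               sum(lb2$labels > 0))
  # voxels of wave k are exactly the label-k support
  for (w in ws2) {
    lin <- (w$coords[, 3] - 1) * 100 + (w$coords[, 2] - 1) * 10 + w$coords[, 1]
    expect_setequal(lin, which(lb2$labels == w$wave_id))
  }

  empty <- segment_waves(array(0L, c(4, 4, 4)))
  expect_length(extract_waves(empty), 0)
})
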