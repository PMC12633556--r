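test_that("flips reflect pixel positions without touching values", {
  mv <- toy_movie(nx = 6, ny = 4, nt = 3)
  mv$data[1, 2, 1] <- 7
  out <- align(mv, orientation_spec(flip_x = TRUE))
  expect_equal(out$data[6, 2, 1], 7)
  expect_equal(sum(out$data), 7)

  ident <- align(mv, orientation_spec())
  expect_identical(ident$data, mv$data)
})

test_that("alignment is an involution and preserves the value histogram", {
  set.seed(21)
  for (i in 1:5) {
    mv <- toy_movie(nx = 5, ny = 7, nt = 4)
    mv$data[] <- rpois(length(mv$data), 0.5)
    fx <- orientation_spec(flip_x = TRUE)
    fy <- orientation_spec(flip_y = TRUE)
    expect_identical(align(align(mv, fx), fx)$data, mv$data)
    expect_identical(align(align(mv, fy), fy)$data, mv$data)
    both <- orientation_spec(flip_x = TRUE, flip_y = TRUE)
    expect_equal(sort(as.vector(align(mv, both)$data)),
                 sort(as.vector(mv$data)))
  }
})

test_that("applying a spec then its inverse is the identity", {
  set.seed(22)
  mv <- toy_movie(nx = 8, ny = 8, nt = 3)
  # keep activity interior so offsets never push pixels off the grid
  mv$data[3:6, 3:6, ] <- rpois(4 * 4 * 3, 1)
  sp <- orientation_spec(flip_x = TRUE, offset_x = 1, offset_y = -2)
  back <- align(align(mv, sp), invert_orientation(sp))
  expect_equal(back$data, mv$data)
})

test_that("offsets move the valid mask identically and invalidate vacated pixels", {
  mv <- toy_movie(nx = 4, ny = 4, nt = 2)
  mv$valid_mask[1, 1] <- FALSE
  out <- align(mv, orientation_spec(offset_x = 2))
  expect_false(out$valid_mask[3, 1])      # moved invalid pixel
  expect_false(any(out$valid_mask[1:2, ]))  # vacated columns
  expect_true(all(out$valid_mask[3:4, ][-1]))
})
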