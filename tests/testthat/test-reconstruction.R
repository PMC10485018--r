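# IDW and biharmonic reconstruction from sparse measurements.

test_that("IDW degenerates to a constant for a single measurement", {
  m <- measurement_set(cbind(3L, 4L), 0.7, c(8L, 8L))
  rec <- idw_reconstruct(m)
  expect_true(all(rec == 0.7))
})

test_that("equidistant measurements average with equal weights", {
  m <- measurement_set(rbind(c(1L, 1L), c(1L, 5L)), c(0, 1), c(5L, 5L))
  rec <- idw_reconstruct(m)
  expect_equal(rec[1L, 3L], 0.5, tolerance = 1e-12)
})

test_that("tree-based IDW matches the brute-force oracle exactly", {
  for (seed in 1:4) {
    m <- random_ms(15L, 15L, 20L, seed)
    expect_lt(max(abs(idw_reconstruct(m) - brute_idw(m))), 1e-10)
  }
  # full-set IDW flag
  m <- random_ms(12L, 12L, 15L, 9L)
  expect_lt(max(abs(idw_reconstruct(m, all_points = TRUE) -
                      brute_idw(m, k = 15L))), 1e-10)
})

test_that("IDW passes through measured pixels and stays within measured bounds", {
  m <- random_ms(20L, 20L, 30L, 5L)
  rec <- idw_reconstruct(m)
  rows <- m$grid[1L]
  lin <- (m$coords[, 2L] - 1L) * rows + m$coords[, 1L]
  expect_lt(max(abs(rec[lin] - m$values)), 1e-12)
  expect_gte(min(rec), min(m$values))
  expect_lte(max(rec), max(m$values))
})

test_that("reconstruction from an empty measurement set is an error", {
  expect_error(measurement_set(matrix(integer(0), 0, 2), numeric(0),
                               c(5L, 5L)) |> idw_reconstruct(),
               "empty")
  expect_error(measurement_set(matrix(integer(0), 0, 2), numeric(0),
                               c(5L, 5L)) |> biharmonic_inpaint(),
               "empty")
})

test_that("biharmonic inpainting is exact on fully measured grids and constants", {
  set.seed(2)
  img <- matrix(runif(100), 10L, 10L)
  m <- ms_from_mask(img, matrix(TRUE, 10L, 10L))
  expect_equal(matrix(biharmonic_inpaint(m), 10L, 10L), img)
  # single interior hole in a constant image
  cimg <- matrix(0.4, 12L, 12L)
  mask <- matrix(TRUE, 12L, 12L); mask[6L, 7L] <- FALSE
  rec <- biharmonic_inpaint(ms_from_mask(cimg, mask))
  expect_lt(abs(rec[6L, 7L] - 0.4), 1e-6)
})

test_that("biharmonic inpainting reproduces a linear ramp", {
  rows <- 20L; cols <- 20L
  ramp <- matrix(rep(seq_len(cols) / cols, each = rows), rows, cols)
  set.seed(3)
  m <- ms_from_indices(ramp, sample(rows * cols, 50L))
  rec <- biharmonic_inpaint(m)
  expect_lt(max(abs(rec - ramp)), 1e-3)
  # measured pixels pass through exactly
  lin <- (m$coords[, 2L] - 1L) * rows + m$coords[, 1L]
  expect_lt(max(abs(rec[lin] - m$values)), 1e-10)
})

test_that("measurement sets reject duplicates and out-of-grid locations", {
  expect_error(measurement_set(rbind(c(1L, 1L), c(1L, 1L)), c(0, 1),
                               c(5L, 5L)), "duplicate")
  expect_error(measurement_set(cbind(6L, 1L), 0.5, c(5L, 5L)), "outside")
})
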