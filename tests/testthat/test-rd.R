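# Reduction-in-distortion targets and training-set construction.

test_that("RD is zero when the reconstruction is already exact", {
  img <- matrix(0.5, 12L, 12L)       # constant truth: IDW is exact everywhere
  m <- ms_from_indices(img, c(10L, 50L, 90L, 130L))
  expect_identical(compute_rd(img, m, c(6L, 6L), window = Inf), 0)
})

test_that("RD equals the squared estimate error for the last unmeasured pixel", {
  set.seed(8)
  img <- matrix(runif(64L), 8L, 8L)
  mask <- matrix(TRUE, 8L, 8L); mask[4L, 5L] <- FALSE
  m <- ms_from_mask(img, mask)
  est <- idw_reconstruct(m)[4L, 5L]
  delta <- img[4L, 5L] - est
  expect_equal(compute_rd(img, m, c(4L, 5L), window = Inf), delta^2,
               tolerance = 1e-12)
})

test_that("full-window RD matches brute-force recomputation exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(runif(400L), 20L, 20L)
    idx <- sample(400L, 40L)
    m <- ms_from_indices(img, idx)
    un <- setdiff(seq_len(400L), idx)
    for (i in sample(un, 10L)) {
      px <- c((i - 1L) %% 20L + 1L, (i - 1L) %/% 20L + 1L)
      expect_equal(compute_rd(img, m, px, window = Inf),
                   brute_rd(img, m, px), tolerance = 1e-10)
    }
  }
})

test_that("the default local window captures most of the full RD", {
  set.seed(4)
  img <- matrix(runif(400L), 20L, 20L)
  idx <- sample(400L, 60L)
  m <- ms_from_indices(img, idx)
  un <- setdiff(seq_len(400L), idx)
  full <- vapply(un, function(i)
    compute_rd(img, m, c((i - 1L) %% 20L + 1L, (i - 1L) %/% 20L + 1L),
               window = Inf), numeric(1L))
  win <- vapply(un, function(i)
    compute_rd(img, m, c((i - 1L) %% 20L + 1L, (i - 1L) %/% 20L + 1L)),
    numeric(1L))
  # windowed and full-image RD agree in aggregate on small grids
  expect_lt(sum(abs(win - full)) / sum(abs(full)), 0.2)
  expect_gt(cor(win, full), 0.95)
})

test_that("RD is refused at measured pixels", {
  img <- matrix(runif(100L), 10L, 10L)
  m <- ms_from_indices(img, c(5L, 50L))
  expect_error(compute_rd(img, m, c(5L, 1L)), "measured")
})

test_that("training sets honor the documented defaults and counting contract", {
  expect_equal(eval(formals(build_training_set)$coverage_levels),
               seq(0.01, 0.80, length.out = 10L))
  img <- generic_training_image(32L)
  ts <- build_training_set(img, coverage_levels = c(0.05, 0.2),
                           masks_per_level = 2L, pairs_per_mask = 50L,
                           seed = 6L)
  expect_equal(length(ts$rd), 2L * 2L * 50L)
  expect_equal(dim(ts$features), c(200L, 6L))
  ts2 <- build_training_set(img, coverage_levels = c(0.05, 0.2),
                            masks_per_level = 2L, pairs_per_mask = 50L,
                            seed = 6L)
  expect_identical(ts, ts2)
  expect_error(build_training_set(img, coverage_levels = c(0, 0.5)),
               "coverage")
})

test_that("approximate RD targets are non-negative and finite", {
  img <- generic_training_image(32L)
  ts <- build_training_set(img, coverage_levels = 0.1, masks_per_level = 1L,
                           pairs_per_mask = 100L, seed = 2L,
                           target = "approximate")
  expect_true(all(is.finite(ts$rd)))
  expect_true(all(ts$rd >= 0))
})
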