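# ROI integration and center-of-mass analysis of diffraction stacks.

test_that("ROI integration sums exactly what lies inside the ROI", {
  pat <- matrix(0, 16L, 16L)
  pat[5L, 7L] <- 2
  roi <- detector_roi(4L, 9L, 6L, 9L)
  expect_identical(roi_integrate(pat, roi), 2)
  expect_identical(roi_integrate(pat, detector_roi(10L, 16L, 10L, 16L)), 0)
  # a centered Gaussian of unit mass is captured by a wide ROI
  g <- outer(dnorm(1:16, 8.5, 1.2), dnorm(1:16, 8.5, 1.2))
  g <- g / sum(g)
  expect_gt(roi_integrate(g, detector_roi(1L, 17L, 1L, 17L)), 0.99)
  expect_error(roi_integrate(pat, detector_roi(10L, 20L, 1L, 5L)), "bounds")
})

test_that("pattern centers of mass report signed shifts from the nominal center", {
  roi <- detector_roi(1L, 17L, 1L, 17L)
  nominal <- c(8.5, 8.5)
  g <- outer(dnorm(1:16, 8.5, 1.5), dnorm(1:16, 8.5, 1.5))
  cm <- pattern_com(g, roi, nominal)
  expect_lt(abs(cm$comx), 1e-6)
  expect_lt(abs(cm$comy), 1e-6)
  # point mass at nominal + (-2 rows, +3 cols)
  p <- matrix(0, 16L, 16L)
  p[7L, 12L] <- 1   # nominal (8.5, 8.5) -> offsets (-1.5, +3.5)
  cm2 <- pattern_com(p, roi, c(8.5, 8.5))
  expect_equal(cm2$comx, 3.5, tolerance = 1e-12)
  expect_equal(cm2$comy, -1.5, tolerance = 1e-12)
  # two equal masses symmetric about the nominal column cancel in comx
  q <- matrix(0, 16L, 16L)
  q[8L, 5L] <- 1; q[8L, 12L] <- 1   # cols 5 and 12 around 8.5
  expect_equal(pattern_com(q, roi, c(8.5, 8.5))$comx, 0, tolerance = 1e-12)
  expect_error(pattern_com(matrix(0, 16L, 16L), roi, nominal), "undefined")
})

test_that("translating a pattern shifts the center of mass linearly", {
  roi <- detector_roi(1L, 25L, 1L, 25L)
  base <- matrix(0, 24L, 24L)
  base[10:12, 9:11] <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3L)
  cm0 <- pattern_com(base, roi, c(12.5, 12.5))
  shifted <- matrix(0, 24L, 24L)
  shifted[13:15, 13:15] <- base[10:12, 9:11]   # translate by (+3, +4)
  cm1 <- pattern_com(shifted, roi, c(12.5, 12.5))
  expect_equal(cm1$comy - cm0$comy, 3, tolerance = 1e-12)
  expect_equal(cm1$comx - cm0$comx, 4, tolerance = 1e-12)
})

test_that("hot pixels are median-clipped without disturbing the peak", {
  g <- outer(dnorm(1:16, 8, 1.5), dnorm(1:16, 8, 1.5))
  spiked <- g
  spiked[2L, 14L] <- 100 * max(g)
  cleaned <- filter_hot_pixels(spiked)
  expect_lt(cleaned[2L, 14L], max(g))
  expect_equal(cleaned[6:10, 6:10], g[6:10, 6:10], tolerance = 1e-12)
})

test_that("CoM maps from a full scan are consistent and sign-antisymmetric across a bubble", {
  cfg <- simulator_config(36L, 36L, n_flakes = 1L, n_bubbles_per_flake = 1L,
                          bubble_radius_range = c(6, 6),
                          flake_area_fraction = 0.5, seed = 19L)
  stack <- generate_diffraction_stack(cfg, det_rows = 24L, det_cols = 24L,
                                      shift_gain = 3)
  img <- generate_flake_image(cfg)
  roi <- detector_roi(1L, 25L, 1L, 25L)
  full <- matrix(TRUE, 36L, 36L)
  maps <- com_maps_from_scan(stack, full, roi)
  # full mask: inpainted equals sparse at every valid pixel
  v <- maps$sparse$valid
  expect_lt(max(abs(maps$inpainted$comx[v] - maps$sparse$comx[v])), 1e-9)
  expect_lt(max(abs(maps$inpainted$comy[v] - maps$sparse$comy[v])), 1e-9)
  # zero-intensity pixels are flagged invalid, not zero
  expect_false(any(maps$sparse$valid[img == 0]))
  # comx changes sign across the bubble's vertical midline
  bub <- attr(img, "bubbles")[[1L]]
  ctr <- round(bub$center)
  rr <- max(1L, ctr[1L] - 5L):min(36L, ctr[1L] + 5L)
  left_cols <- max(1L, ctr[2L] - 6L):(ctr[2L] - 1L)
  right_cols <- (ctr[2L] + 1L):min(36L, ctr[2L] + 6L)
  cx <- maps$sparse$comx
  left_sum <- sum(cx[rr, left_cols][v[rr, left_cols]])
  right_sum <- sum(cx[rr, right_cols][v[rr, right_cols]])
  expect_lt(left_sum * right_sum, 0)
  expect_lt(abs(left_sum + right_sum) / max(abs(left_sum), abs(right_sum)),
            0.2)
  expect_error(com_maps_from_scan(stack, matrix(FALSE, 36L, 36L), roi),
               "empty")
})
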