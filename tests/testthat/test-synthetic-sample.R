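# Simulated instrument: flake scenes, diffraction stacks, point measurements.

test_that("empty scene equals the background and generation is deterministic", {
  cfg <- simulator_config(30, 40, n_flakes = 0L, background_level = 0.2,
                          seed = 5L)
  img <- generate_flake_image(cfg)
  expect_true(all(img == 0.2))
  cfg2 <- simulator_config(64, 64, seed = 9L)
  expect_identical(generate_flake_image(cfg2), generate_flake_image(cfg2))
})

test_that("a single flake covers roughly its target area fraction", {
  cfg <- simulator_config(100, 100, n_flakes = 1L, n_bubbles_per_flake = 0L,
                          flake_area_fraction = 0.3, seed = 3L)
  img <- generate_flake_image(cfg)
  frac <- mean(img > 0)
  expect_gte(frac, 0.2)
  expect_lte(frac, 0.4)
})

test_that("flake images stay in [0,1], use the configured levels, and have dark rims", {
  cfg <- simulator_config(80, 80, n_flakes = 2L, n_bubbles_per_flake = 1L,
                          rim_contrast = 0.8, seed = 12L)
  img <- generate_flake_image(cfg)
  expect_true(all(is.finite(img)))
  expect_gte(min(img), 0)
  expect_lte(max(img), 1)
  vals <- setdiff(unique(as.numeric(img)), 0)
  lv <- cfg$thickness_levels
  expect_true(all(vals %in% c(lv, lv * (1 - cfg$rim_contrast))))
  bubbles <- attr(img, "bubbles")
  expect_gt(length(bubbles), 0L)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(simulator_config(0, 10), "positive")
  expect_error(simulator_config(20, 20, bubble_radius_range = c(5, 15)),
               "radius")
  expect_error(simulator_config(20, 20, thickness_levels = c(0.9, 0.1)),
               "sorted")
})

test_that("point measurement honors the noise model and grid bounds", {
  img <- matrix(0.73, 5, 5)
  expect_identical(measure_point(img, c(2, 3)), 0.73)
  expect_error(measure_point(img, c(6, 1)), "outside")
  # poisson at high count rate is nearly exact in the mean
  img2 <- matrix(0.5, 3, 3)
  set.seed(42)
  draws <- replicate(1000, measure_point(img2, c(1, 1),
                                         noise_model("poisson", 1e6)))
  expect_lt(abs(mean(draws) - 0.5) / 0.5, 0.01)
  # gaussian noise never drives a zero pixel negative
  img3 <- matrix(0, 3, 3)
  set.seed(43)
  g <- replicate(500, measure_point(img3, c(2, 2),
                                    noise_model("gaussian", 0.1)))
  expect_true(all(g >= 0))
})

test_that("diffraction patterns sit at the nominal center in flat regions and are empty in background", {
  cfg <- simulator_config(40, 40, n_flakes = 1L, n_bubbles_per_flake = 1L,
                          bubble_radius_range = c(5, 5),
                          flake_area_fraction = 0.4, seed = 7L)
  stack <- generate_diffraction_stack(cfg, det_rows = 24L, det_cols = 24L)
  img <- generate_flake_image(cfg)
  roi <- detector_roi(1, 25, 1, 25)
  flat <- which(img > 0.01)
  bub <- attr(img, "bubbles")[[1L]]
  d2 <- outer(seq_len(40) - bub$center[1L], seq_len(40) - bub$center[2L],
              function(a, b) sqrt(a^2 + b^2))
  flat <- flat[d2[flat] > bub$radius + 1]   # outside the bubble: zero gradient
  px <- arrayInd(flat[1L], c(40L, 40L))
  cm <- pattern_com(stack$patterns[px[1L], px[2L], , ], roi,
                    stack$nominal_center)
  expect_lt(abs(cm$comx), 1e-6)
  expect_lt(abs(cm$comy), 1e-6)
  bg <- which(img == 0)[1L]
  pxb <- arrayInd(bg, c(40L, 40L))
  expect_true(all(stack$patterns[pxb[1L], pxb[2L], , ] == 0))
})

test_that("excessive peak shifts are clipped to the detector with a warning", {
  cfg <- simulator_config(30L, 30L, n_flakes = 1L, n_bubbles_per_flake = 1L,
                          bubble_radius_range = c(6, 6),
                          flake_area_fraction = 0.5, seed = 19L)
  expect_warning(stack <- generate_diffraction_stack(cfg, det_rows = 16L,
                                                     det_cols = 16L,
                                                     shift_gain = 100),
                 "clipped")
  expect_true(all(is.finite(stack$patterns)))
  expect_true(all(stack$patterns >= 0))
})

test_that("bubble shifts are antisymmetric and ROI integrals reproduce the image", {
  cfg <- simulator_config(40, 40, n_flakes = 1L, n_bubbles_per_flake = 1L,
                          bubble_radius_range = c(6, 6),
                          flake_area_fraction = 0.5, seed = 19L)
  stack <- generate_diffraction_stack(cfg, det_rows = 24L, det_cols = 24L,
                                      shift_gain = 3)
  img <- generate_flake_image(cfg)
  roi <- detector_roi(1, 25, 1, 25)
  bub <- attr(img, "bubbles")[[1L]]
  ctr <- round(bub$center)
  off <- floor(bub$radius * 0.6)
  left <- c(ctr[1L], ctr[2L] - off); right <- c(ctr[1L], ctr[2L] + off)
  cml <- pattern_com(stack$patterns[left[1L], left[2L], , ], roi,
                     stack$nominal_center)
  cmr <- pattern_com(stack$patterns[right[1L], right[2L], , ], roi,
                     stack$nominal_center)
  expect_gt(abs(cml$comx), 0.05)
  expect_lt(abs(cml$comx + cmr$comx), 1e-6)   # equal magnitude, opposite sign
  # consistency: ROI-integrated intensities reproduce the dark-field image
  integ <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    integ[i, j] <- roi_integrate(stack$patterns[i, j, , ], roi)
  }
  expect_lt(sqrt(mean((integ - img)^2)), 0.01)
})
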