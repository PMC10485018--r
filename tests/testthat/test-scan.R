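# Batch selection, stopping rules, and the closed acquisition loop.

test_that("batch selection is a descending top-k with lexicographic ties", {
  set.seed(12)
  erd <- matrix(runif(400L), 20L, 20L)
  measured <- sample(400L, 100L)
  erd[measured] <- NA_real_
  sel <- select_batch(erd, 10L)
  un <- which(!is.na(erd))
  ord <- order(-erd[un], (un - 1L) %% 20L + 1L, (un - 1L) %/% 20L + 1L)
  top <- un[ord[1:10]]
  expect_identical((sel[, 2L] - 1L) * 20L + sel[, 1L], top)
  # exhaustion: a single unmeasured pixel
  erd2 <- matrix(NA_real_, 5L, 5L); erd2[3L, 4L] <- 1
  expect_identical(select_batch(erd2, 50L), cbind(3L, 4L))
  # tie break on constant maps is (row, col) lexicographic
  erd3 <- matrix(1, 4L, 4L)
  sel3 <- select_batch(erd3, 3L)
  expect_identical(sel3, cbind(c(1L, 1L, 1L), c(1L, 2L, 3L)))
  expect_identical(eval(formals(scan_config)$batch_size), 50L)
  expect_identical(eval(formals(scan_config)$initial_fraction), 0.01)
})

test_that("stopping rules react to coverage and ERD plateaus", {
  it <- data.frame(coverage = c(0.05, 0.08), total_erd = c(10, 9))
  expect_false(check_stopping(it, stopping_rule("coverage_only"),
                              max_coverage = 0.35))
  expect_true(check_stopping(data.frame(coverage = 0.35, total_erd = 1),
                             stopping_rule("coverage_only"),
                             max_coverage = 0.35))
  # constant total ERD triggers any plateau tolerance once the window fills
  rule <- stopping_rule("erd_plateau", window = 3L, rel_tolerance = 0.01)
  it2 <- data.frame(coverage = seq(0.02, 0.10, by = 0.02),
                    total_erd = rep(5, 5L))
  expect_true(check_stopping(it2, rule, max_coverage = 1))
  expect_false(check_stopping(it2[1:2, ], rule, max_coverage = 1))
  # 1/i decay triggers exactly where the windowed relative change drops
  e <- 1 / (1:40)
  rule2 <- stopping_rule("erd_plateau", window = 3L, rel_tolerance = 0.05)
  trigger <- vapply(seq_along(e), function(i) {
    it <- data.frame(coverage = seq_len(i) / 100, total_erd = e[seq_len(i)])
    check_stopping(it, rule2, max_coverage = 1)
  }, logical(1L))
  # scalar oracle: windowed relative change of the same sequence
  oracle <- vapply(seq_along(e), function(i) {
    if (i < 3L) return(FALSE)
    w <- e[(i - 2L):i]
    (max(w) - min(w)) / max(abs(w)) < 0.05
  }, logical(1L))
  expect_identical(trigger, oracle)
})

test_that("the adaptive loop measures in exact batch increments without repeats", {
  mod <- tiny_model()
  img <- generate_flake_image(simulator_config(40L, 40L, seed = 3L))
  cfg <- scan_config(initial_fraction = 0.01, batch_size = 25L,
                     max_coverage = 0.12, seed = 5L)
  tr <- run_fast_scan(img, mod, cfg)
  n_init <- nrow(hammersley_points(c(40L, 40L), 0.01))
  target <- as.integer(round(0.12 * 1600))
  # full batches until the final one, which is trimmed to the coverage target
  expect_identical(tr$iterations$n_measured,
                   pmin(n_init + tr$iterations$iteration * 25L, target))
  lin <- (tr$measurements$coords[, 2L] - 1L) * 40L + tr$measurements$coords[, 1L]
  expect_identical(anyDuplicated(lin), 0L)
  expect_true(all(diff(tr$iterations$coverage) > 0))
  expect_equal(nrow(tr$measurements$coords), target)
  # optimized batch routes never exceed the ERD-descending input order
  expect_true(all(tr$iterations$route_length <=
                    tr$iterations$route_length_input + 1e-9))
})

test_that("full coverage with exact measurement reproduces the sample", {
  mod <- tiny_model()
  img <- generate_flake_image(simulator_config(16L, 16L, seed = 6L))
  cfg <- scan_config(initial_fraction = 0.05, batch_size = 40L,
                     max_coverage = 1, seed = 2L)
  tr <- run_fast_scan(img, mod, cfg)
  expect_equal(matrix(tr$final_idw, 16L, 16L), matrix(img, 16L, 16L),
               ignore_attr = TRUE)
  expect_equal(matrix(tr$final_biharmonic, 16L, 16L),
               matrix(img, 16L, 16L), ignore_attr = TRUE)
})

test_that("checkpoint snapshots capture the measurement state at requested coverages", {
  mod <- tiny_model()
  img <- generate_flake_image(simulator_config(32L, 32L, seed = 8L))
  cfg <- scan_config(batch_size = 30L, max_coverage = 0.2,
                     checkpoint_coverages = c(0.05, 0.1), seed = 3L)
  tr <- run_fast_scan(img, mod, cfg)
  expect_named(tr$checkpoints, c("0.05", "0.1"))
  expect_gte(nrow(tr$checkpoints[["0.05"]]$coords), round(0.05 * 1024))
  expect_lt(nrow(tr$checkpoints[["0.05"]]$coords),
            nrow(tr$checkpoints[["0.1"]]$coords))
  # snapshots are prefixes of the final acquisition order
  n5 <- nrow(tr$checkpoints[["0.05"]]$coords)
  expect_identical(tr$checkpoints[["0.05"]]$coords,
                   tr$measurements$coords[seq_len(n5), ])
})

test_that("noisy measurements are reproducible under the scan seed", {
  mod <- tiny_model()
  img <- generate_flake_image(simulator_config(24L, 24L, seed = 4L))
  cfg <- scan_config(batch_size = 20L, max_coverage = 0.1, seed = 77L)
  nz <- noise_model("gaussian", 0.02)
  t1 <- run_fast_scan(img, mod, cfg, noise = nz)
  t2 <- run_fast_scan(img, mod, cfg, noise = nz)
  expect_identical(t1$measurements$values, t2$measurements$values)
  expect_identical(t1$iterations, t2$iterations)
})
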