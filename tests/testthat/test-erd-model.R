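# The ERD regressor: training behavior, prediction contracts, serialization.

test_that("training reduces the loss and records the documented defaults", {
  expect_identical(eval(formals(train_erd_model)$epochs), 100L)
  expect_identical(eval(formals(train_erd_model)$learning_rate), 0.001)
  mod <- tiny_model()
  lh <- mod$training_meta$loss_history
  expect_lte(lh[length(lh)], lh[1L])
  # architecture: 5 hidden layers of 50 plus scalar output
  widths <- vapply(mod$layers, function(l) ncol(l$W), integer(1L))
  expect_identical(widths, c(50L, 50L, 50L, 50L, 50L, 1L))
})

test_that("the network recovers a simple synthetic regression rule", {
  set.seed(14)
  n <- 4000L
  X <- cbind(grad_x = rnorm(n, 0, 0.1), grad_y = rnorm(n, 0, 0.1),
             sigma1 = runif(n, 0, 0.5), sigma2 = runif(n, 0, 0.25),
             nearest_dist = runif(n, 0.5, 8), density = runif(n))
  y <- 2 * X[, "nearest_dist"] + rnorm(n, 0, 0.3)
  tr <- seq_len(3000L)
  mod <- train_erd_model(list(features = X[tr, ], rd = y[tr]),
                         epochs = 60L, seed = 3L)
  pred <- predict(mod, X[-tr, ])
  r2 <- 1 - mean((pred - y[-tr])^2) / var(y[-tr])
  expect_gt(r2, 0.8)
})

test_that("training rejects degenerate inputs", {
  X <- matrix(rnorm(60L), 10L, 6L)
  expect_error(train_erd_model(list(features = X, rd = rnorm(10L))),
               "at least 100")
  expect_error(train_erd_model(list(features = NULL, rd = NULL)), "features")
})

test_that("ERD maps cover exactly the unmeasured pixels, non-negatively", {
  mod <- tiny_model()
  set.seed(21)
  img <- generate_flake_image(simulator_config(24L, 24L, seed = 2L))
  mask <- matrix(TRUE, 24L, 24L)
  un <- sample(576L, 40L)
  mask[un] <- FALSE
  m <- ms_from_mask(img, mask)
  erd <- predict_erd(mod, m, idw_reconstruct(m))
  expect_identical(which(is.na(erd)), setdiff(seq_len(576L), sort(un)))
  expect_true(all(erd[un] >= 0))
  # single remaining pixel: the map is defined exactly there
  mask2 <- matrix(TRUE, 24L, 24L); mask2[10L, 11L] <- FALSE
  m2 <- ms_from_mask(img, mask2)
  erd2 <- predict_erd(mod, m2, idw_reconstruct(m2))
  expect_identical(which(!is.na(erd2)), (11L - 1L) * 24L + 10L)
  # fully measured: error
  m3 <- ms_from_mask(img, matrix(TRUE, 24L, 24L))
  expect_error(predict_erd(mod, m3, idw_reconstruct(m3)), "fully measured")
})

test_that("batch prediction equals one-at-a-time prediction", {
  mod <- tiny_model()
  set.seed(31)
  X <- cbind(rnorm(20L, 0, 0.1), rnorm(20L, 0, 0.1), runif(20L, 0, 0.4),
             runif(20L, 0, 0.2), runif(20L, 0.5, 6), runif(20L))
  batch <- predict(mod, X)
  single <- vapply(seq_len(20L), function(i) predict(mod, X[i, ]),
                   numeric(1L))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("model serialization round-trips predictions exactly", {
  mod <- tiny_model()
  path <- tempfile(fileext = ".json")
  write_erd_model(mod, path)
  mod2 <- read_erd_model(path)
  set.seed(41)
  X <- cbind(rnorm(50L, 0, 0.1), rnorm(50L, 0, 0.1), runif(50L, 0, 0.4),
             runif(50L, 0, 0.2), runif(50L, 0.5, 6), runif(50L))
  expect_identical(predict(mod2, X), predict(mod, X))
  expect_identical(mod2$center, unname(mod$center))
  expect_identical(mod2$scale, unname(mod$scale))
  unlink(path)
})
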