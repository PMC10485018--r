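# The ERD regressor: standardized features -> fixed random Fourier feature
# kernelization -> fully connected network (5 hidden layers x 50 ReLU units,
# scalar output) trained with Adam on mean squared error against RD targets.

# ---- minimal MLP internals -------------------------------------------------

#' @keywords internal
mlp_init <- function(dims, seed) {
  with_seed(seed, {
    layers <- vector("list", length(dims) - 1L)
    for (i in seq_along(layers)) {
      fan_in <- dims[i]
      layers[[i]] <- list(
        W = matrix(stats::rnorm(dims[i] * dims[i + 1L], 0,
                                sqrt(2 / fan_in)),
                   dims[i], dims[i + 1L]),
        b = numeric(dims[i + 1L]))
    }
  })
  layers
}

# Forward pass; keeps activations when `keep = TRUE` (for backprop).
#' @keywords internal
mlp_forward <- function(layers, X, keep = FALSE) {
  L <- length(layers)
  acts <- if (keep) vector("list", L + 1L) else NULL
  a <- X
  if (keep) acts[[1L]] <- a
  n <- nrow(X)
  for (i in seq_len(L)) {
    z <- a %*% layers[[i]]$W + rep(layers[[i]]$b, each = n)
    a <- if (i < L) pmax(z, 0) else z     # ReLU hidden, linear output
    if (keep) acts[[i + 1L]] <- a
  }
  if (keep) list(out = drop(a), acts = acts) else drop(a)
}

# Gradient of 0.5 * mean squared error wrt all weights.
#' @keywords internal
mlp_grad <- function(layers, acts, resid) {
  L <- length(layers)
  n <- length(resid)
  grads <- vector("list", L)
  delta <- matrix(resid / n, ncol = 1L)
  for (i in L:1) {
    a_prev <- acts[[i]]
    grads[[i]] <- list(W = crossprod(a_prev, delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
    }
  }
  grads
}

# ---- fitting ---------------------------------------------------------------

#' Train the ERD decision model
#'
#' Fits the expected-reduction-in-distortion regressor g(v): feature vectors
#' are standardized (constants frozen from the training set), lifted with a
#' fixed random-Fourier-feature Gaussian kernel map, and fed to a fully
#' connected network with 5 hidden layers of 50 ReLU units and a scalar
#' linear output, trained for `epochs` epochs of minibatch Adam on mean
#' squared error against the RD targets.
#'
#' @param pairs A [build_training_set()] result, or a list with `features`
#'   (n x 6 matrix) and `rd` (length-n vector); at least 100 pairs.
#' @param epochs Training epochs (default 100).
#' @param learning_rate Adam step size (default 0.001).
#' @param cfg A [feature_config()] fixing k, radius policy and the
#'   kernelization.
#' @param hidden Hidden layer widths (default `rep(50, 5)`).
#' @param batch_size Minibatch size (default 1024; large batches keep the
#'   per-step overhead low on CPU BLAS).
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @return An object of class `erd_model`.
#' @export
train_erd_model <- function(pairs, epochs = 100L, learning_rate = 0.001,
                            cfg = feature_config(), hidden = rep(50L, 5L),
                            batch_size = 1024L, seed = 99L) {
  X <- pairs$features; y <- pairs$rd
  stop_if(is.null(X) || is.null(y), "pairs must carry $features and $rd")
  stop_if(length(y) == 0L, "empty training set")
  stop_if(length(y) < 100L, "need at least 100 training pairs")
  stop_if(!all(is.finite(X)) || !all(is.finite(y)),
          "non-finite training values")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  map <- rbf_map(cfg)
  Z <- kernelize(sweep(sweep(X, 2L, center), 2L, scale, "/"), map)
  dims <- c(cfg$rbf_dim, hidden, 1L)
  layers <- mlp_init(dims, substream_seed(seed, 1L))
  nlay <- length(layers)
  # Adam state kept as flat vectors (one update per step instead of one per
  # parameter tensor); layer matrices are refreshed from the flat vector
  theta <- unlist(lapply(layers, function(l) c(l$W, l$b)))
  sizes <- lapply(layers, function(l) c(length(l$W), length(l$b)))
  madam <- numeric(length(theta)); vadam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- length(y)
  step <- 0L
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(substream_seed(seed, 100L + ep), sample.int(n))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, n)]
      fw <- mlp_forward(layers, Z[bi, , drop = FALSE], keep = TRUE)
      resid <- fw$out - y[bi]
      ep_loss <- ep_loss + mean(resid^2); nb <- nb + 1L
      grads <- mlp_grad(layers, fw$acts, resid)
      g <- unlist(lapply(grads, function(l) c(l$W, l$b)))
      step <- step + 1L
      madam <- b1 * madam + (1 - b1) * g
      vadam <- b2 * vadam + (1 - b2) * g^2
      theta <- theta - learning_rate * (madam / (1 - b1^step)) /
        (sqrt(vadam / (1 - b2^step)) + eps)
      pos <- 0L
      for (i in seq_len(nlay)) {
        layers[[i]]$W[] <- theta[(pos + 1L):(pos + sizes[[i]][1L])]
        pos <- pos + sizes[[i]][1L]
        layers[[i]]$b <- theta[(pos + 1L):(pos + sizes[[i]][2L])]
        pos <- pos + sizes[[i]][2L]
      }
    }
    loss_history[ep] <- ep_loss / nb
  }
  structure(list(rbf = map, center = center, scale = scale,
                 layers = layers, cfg = cfg,
                 training_meta = list(epochs = epochs,
                                      learning_rate = learning_rate,
                                      batch_size = batch_size,
                                      n_pairs = n, seed = seed,
                                      loss_history = loss_history)),
            class = "erd_model")
}

#' Predict raw ERD values for feature vectors
#'
#' Low-level prediction: standardizes, kernelizes and evaluates the network.
#' Values are unclipped (may be negative); the acquisition loop clips at 0.
#'
#' @param object An `erd_model`.
#' @param newdata n x 6 feature matrix (or length-6 vector).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.erd_model <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, 1L) else newdata
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  mlp_forward(object$layers, kernelize(xs, object$rbf))
}

#' @export
print.erd_model <- function(x, ...) {
  widths <- vapply(x$layers, function(l) ncol(l$W), integer(1L))
  cat("<erd_model> SLADS-Net ERD regressor\n")
  cat(sprintf("  kernelization: 6 -> %d random Fourier features (gamma = %g)\n",
              x$rbf$dim, x$rbf$gamma))
  cat(sprintf("  network: %s (ReLU hidden, linear output)\n",
              paste(widths, collapse = "-")))
  cat(sprintf("  trained on %d pairs, %d epochs, final MSE %.4g\n",
              x$training_meta$n_pairs, x$training_meta$epochs,
              utils::tail(x$training_meta$loss_history, 1L)))
  invisible(x)
}

#' @export
summary.erd_model <- function(object, ...) {
  lh <- object$training_meta$loss_history
  out <- list(n_pairs = object$training_meta$n_pairs,
              epochs = object$training_meta$epochs,
              learning_rate = object$training_meta$learning_rate,
              initial_loss = lh[1L], final_loss = utils::tail(lh, 1L),
              rbf_dim = object$rbf$dim)
  class(out) <- "summary.erd_model"
  out
}

#' @export
print.summary.erd_model <- function(x, ...) {
  cat(sprintf(paste0("ERD model: %d pairs, %d epochs (lr %g), ",
                     "training MSE %.4g -> %.4g, %d kernel features\n"),
              x$n_pairs, x$epochs, x$learning_rate,
              x$initial_loss, x$final_loss, x$rbf_dim))
  invisible(x)
}

#' @export
plot.erd_model <- function(x, ...) {
  graphics::plot(x$training_meta$loss_history, type = "l",
                 xlab = "epoch", ylab = "training MSE",
                 main = "ERD model training loss", ...)
  invisible(x)
}

#' Predict the ERD map for the current measurement state
#'
#' Evaluates the trained regressor at every unmeasured pixel. Measured pixels
#' carry `NA` (the ERD is undefined there); negative predictions are clipped
#' to 0 so the map is a valid selection score.
#'
#' Pixels whose neighborhood is degenerate — zero reconstruction gradients
#' and zero deviation between the estimate and every nearby measured value —
#' are assigned an exact ERD of 0 without consulting the network: the local
#' measurement state is perfectly interpolated and locally constant, so
#' measuring there cannot reduce the distortion of the local model. This
#' analytic shortcut (analogous to the exact-hit rule in the interpolator)
#' keeps the large homogeneous regions of sparse samples exactly tied at
#' zero instead of carrying network approximation noise.
#'
#' @param model An [train_erd_model()] result.
#' @param m A [measurement_set()] with at least one unmeasured pixel.
#' @param recon Current reconstruction (e.g. [idw_reconstruct()]).
#' @param cfg A [feature_config()]; defaults to the model's.
#' @return Numeric matrix of the grid shape: non-negative at unmeasured
#'   pixels, `NA` at measured ones.
#' @export
predict_erd <- function(model, m, recon, cfg = model$cfg) {
  stopifnot(inherits(model, "erd_model"), inherits(m, "measurement_set"))
  mask <- ms_mask(m)
  un <- which(!mask)
  stop_if(length(un) == 0L, "grid is fully measured; no ERD to predict")
  coords <- index_to_coords(un, m$grid[1L])
  fmat <- compute_feature_matrix(m, recon, coords, cfg)
  pred <- pmax(predict(model, fmat), 0)
  degenerate <- fmat[, "sigma1"] == 0 & fmat[, "sigma2"] == 0 &
    fmat[, "grad_x"] == 0 & fmat[, "grad_y"] == 0
  pred[degenerate] <- 0
  out <- matrix(NA_real_, m$grid[1L], m$grid[2L])
  out[un] <- pred
  out
}

# ---- default, sample-agnostic model ---------------------------------------

#' Train the default sample-agnostic ERD model
#'
#' Builds the training set from the bundled generic photographic test image
#' ([load_training_image()]) — an image with no relation to the flake
#' simulator — and fits the standard model. This is the sample-agnostic
#' configuration: one model, trained once, applied to any scan subject.
#' [generic_training_image()] offers a fully synthetic alternative.
#'
#' @param image Training image (default `load_training_image()`).
#' @param cfg A [feature_config()].
#' @param seed Master seed for mask generation and network training.
#' @param ... Passed to [build_training_set()] (e.g. `masks_per_level`).
#' @return An `erd_model`.
#' @export
train_default_model <- function(image = load_training_image(),
                                cfg = feature_config(), seed = 1L, ...) {
  pairs <- build_training_set(image, cfg = cfg,
                              seed = substream_seed(seed, 11L), ...)
  train_erd_model(pairs, cfg = cfg, seed = substream_seed(seed, 12L))
}

# ---- serialization ---------------------------------------------------------

#' Save / load an ERD model
#'
#' Single-file archive: a JSON document holding a format tag, the
#' kernelization constants, standardization constants, training metadata, and
#' the network weights as a base64-encoded little-endian double block.
#'
#' @param model An `erd_model`.
#' @param path File path.
#' @return `write_erd_model` returns `path` invisibly; `read_erd_model`
#'   returns the restored `erd_model`.
#' @export
write_erd_model <- function(model, path) {
  stopifnot(inherits(model, "erd_model"))
  shapes <- lapply(model$layers, function(l) dim(l$W))
  # kernel map, standardization constants and weights all ride in the binary
  # block so the round trip is bit-exact
  flat <- c(as.numeric(model$rbf$W), model$rbf$b,
            as.numeric(model$center), as.numeric(model$scale),
            unlist(lapply(model$layers, function(l) c(as.numeric(l$W), l$b))))
  doc <- list(
    format = "sladscan-erd-model",
    version = 1L,
    rbf = list(dim = model$rbf$dim, gamma = model$rbf$gamma,
               seed = model$rbf$seed),
    n_features = length(model$center),
    cfg = unclass(model$cfg),
    layer_shapes = shapes,
    training_meta = model$training_meta,
    weights_base64 = jsonlite::base64_enc(writeBin(flat, raw(),
                                                   size = 8L,
                                                   endian = "little")))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_erd_model
#' @export
read_erd_model <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE)
  stop_if(!identical(doc$format, "sladscan-erd-model"),
          "not an ERD model file")
  cfg_radius <- doc$cfg$radius
  cfg <- feature_config(k = doc$cfg$k,
                        radius = if (is.null(cfg_radius)) NULL else cfg_radius,
                        rbf_dim = doc$cfg$rbf_dim,
                        rbf_gamma = doc$cfg$rbf_gamma,
                        rbf_seed = doc$cfg$rbf_seed)
  raw <- jsonlite::base64_dec(doc$weights_base64)
  flat <- readBin(raw, numeric(), n = length(raw) / 8L, size = 8L,
                  endian = "little")
  nf <- doc$n_features
  D <- doc$rbf$dim
  W <- matrix(flat[seq_len(nf * D)], nf, D)
  flat <- flat[-seq_len(nf * D)]
  b <- flat[seq_len(D)]
  flat <- flat[-seq_len(D)]
  map <- list(W = W, b = b, dim = D, gamma = doc$rbf$gamma,
              seed = doc$rbf$seed)
  center <- flat[seq_len(nf)]
  scale <- flat[nf + seq_len(nf)]
  flat <- flat[-seq_len(2L * nf)]
  shapes <- doc$layer_shapes
  if (is.matrix(shapes)) shapes <- split(shapes, row(shapes))
  layers <- list(); pos <- 1L
  for (i in seq_along(shapes)) {
    d <- as.integer(shapes[[i]])
    nW <- d[1L] * d[2L]
    W <- matrix(flat[pos:(pos + nW - 1L)], d[1L], d[2L]); pos <- pos + nW
    b <- flat[pos:(pos + d[2L] - 1L)]; pos <- pos + d[2L]
    layers[[i]] <- list(W = W, b = b)
  }
  tm <- doc$training_meta
  structure(list(rbf = map, center = center, scale = scale,
                 layers = layers, cfg = cfg, training_meta = tm),
            class = "erd_model")
}
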