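# Per-pixel feature vectors describing the local measurement state, and the
# random-Fourier-feature RBF kernelization that lifts them to the network
# input space.

#' Feature configuration for the decision model
#'
#' @param k Number of nearest measured points used in the deviation features
#'   and IDW reconstruction (default 10).
#' @param radius Neighborhood radius r in pixels for the deviation and density
#'   features. `NULL` (default) recomputes it each call as
#'   `0.25 * sqrt(rows * cols / n_measured)` — a quarter of the mean
#'   inter-measurement spacing scale.
#' @param rbf_dim Dimension of the kernelized feature space (default 50).
#' @param rbf_gamma Gaussian kernel width parameter on standardized features.
#'   The default 1/24 follows the median heuristic: for standardized
#'   6-dimensional features the expected squared pair distance is about 12,
#'   and `gamma = 1 / (2 * 12)` puts the kernel bandwidth on that scale.
#' @param rbf_seed Seed fixing the random Fourier feature map (default 7).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(k = 10L, radius = NULL, rbf_dim = 50L,
                           rbf_gamma = 1 / 24, rbf_seed = 7L) {
  stop_if(k < 1, "k must be >= 1")
  stop_if(!is.null(radius) && radius <= 0, "radius must be > 0")
  stop_if(rbf_dim < 1, "rbf_dim must be >= 1")
  stop_if(rbf_gamma <= 0, "rbf_gamma must be > 0")
  structure(list(k = as.integer(k), radius = radius,
                 rbf_dim = as.integer(rbf_dim),
                 rbf_gamma = as.numeric(rbf_gamma),
                 rbf_seed = as.integer(rbf_seed)),
            class = "feature_config")
}

#' @keywords internal
effective_radius <- function(cfg, grid, n_measured) {
  if (!is.null(cfg$radius)) return(cfg$radius)
  max(1, 0.25 * sqrt(prod(grid) / n_measured))
}

# Central-difference gradients of an image; one-sided at the borders.
# gx = d/d col, gy = d/d row.
#' @keywords internal
grad_matrices <- function(img) {
  rows <- nrow(img); cols <- ncol(img)
  gx <- matrix(0, rows, cols); gy <- matrix(0, rows, cols)
  if (cols >= 3L) gx[, 2:(cols - 1L)] <- (img[, 3:cols] - img[, 1:(cols - 2L)]) / 2
  if (cols >= 2L) {
    gx[, 1L] <- img[, 2L] - img[, 1L]
    gx[, cols] <- img[, cols] - img[, cols - 1L]
  }
  if (rows >= 3L) gy[2:(rows - 1L), ] <- (img[3:rows, ] - img[1:(rows - 2L), ]) / 2
  if (rows >= 2L) {
    gy[1L, ] <- img[2L, ] - img[1L, ]
    gy[rows, ] <- img[rows, ] - img[rows - 1L, ]
  }
  list(gx = gx, gy = gy)
}

# Vectorized feature computation for a set of pixels (rows of `pixels`).
# Returns an n x 6 matrix: grad_x, grad_y, sigma1, sigma2, nearest_dist,
# density.
#' @keywords internal
compute_feature_matrix <- function(m, recon, pixels, cfg = feature_config()) {
  rows <- m$grid[1L]
  n_meas <- nrow(m$coords)
  r <- effective_radius(cfg, m$grid, n_meas)
  g <- grad_matrices(recon)
  pidx <- coords_to_index(pixels, rows)
  meas_lin <- coords_to_index(m$coords, rows)
  nn <- knn_measured(m$coords, meas_lin, pixels, cfg$k)
  d <- nn$d
  vals <- matrix(m$values[nn$idx], nrow = nrow(pixels))
  est <- recon[pidx]
  dev <- abs(vals - est)
  w <- d^(-2)
  in_r <- d <= r
  # fall back to all k neighbors when none lie within the radius
  none_in <- rowSums(in_r) == 0L
  w_eff <- w * in_r
  if (any(none_in)) w_eff[none_in, ] <- w[none_in, , drop = FALSE]
  sw <- rowSums(w_eff)
  sigma1 <- rowSums(w_eff * dev) / sw
  sigma2 <- rowSums(w_eff * dev^2) / sw
  dc <- disc_counts(ms_mask(m), r)
  density <- dc$hits[pidx] / dc$total[pidx]
  cbind(grad_x = g$gx[pidx], grad_y = g$gy[pidx],
        sigma1 = sigma1, sigma2 = sigma2,
        nearest_dist = d[, 1L], density = density)
}

#' Compute the 6-dimensional feature vector of an unmeasured pixel
#'
#' The features summarize the local measurement state around pixel P:
#' spatial gradients of the reconstruction at P (`grad_x`, `grad_y`),
#' inverse-distance-weighted mean absolute and squared deviations of the
#' nearby measured values from the estimate at P (`sigma1`, `sigma2`,
#' restricted to radius r with fallback to the k nearest), the distance to
#' the nearest measured point (`nearest_dist`), and the measured fraction of
#' the pixel disc of radius r (`density`).
#'
#' @param m A nonempty [measurement_set()].
#' @param recon Reconstruction of the current state (e.g. [idw_reconstruct()]).
#' @param pixel Length-2 (row, col) of an unmeasured pixel.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 6.
#' @export
compute_features <- function(m, recon, pixel, cfg = feature_config()) {
  stopifnot(inherits(m, "measurement_set"))
  stop_if(nrow(m$coords) == 0L, "measurement set is empty")
  pm <- matrix(as.integer(pixel), ncol = 2L)
  midx <- coords_to_index(m$coords, m$grid[1L])
  stop_if(coords_to_index(pm, m$grid[1L]) %in% midx,
          "pixel (%d, %d) is already measured", pixel[1L], pixel[2L])
  drop(compute_feature_matrix(m, recon, pm, cfg))
}

# Random Fourier feature map approximating a Gaussian kernel
# exp(-gamma ||u - v||^2): z(x) = sqrt(2/D) cos(W'x + b),
# W ~ N(0, 2*gamma), b ~ U(0, 2*pi). Deterministic for a fixed seed.
#' @keywords internal
rbf_map <- function(cfg) {
  with_seed(cfg$rbf_seed, {
    W <- matrix(stats::rnorm(6L * cfg$rbf_dim, 0, sqrt(2 * cfg$rbf_gamma)),
                6L, cfg$rbf_dim)
    b <- stats::runif(cfg$rbf_dim, 0, 2 * pi)
  })
  list(W = W, b = b, dim = cfg$rbf_dim, gamma = cfg$rbf_gamma,
       seed = cfg$rbf_seed)
}

#' RBF kernelization of feature vectors
#'
#' Lifts 6-dimensional feature vectors to `rbf_dim` dimensions with a fixed
#' random Fourier feature map whose inner products approximate the Gaussian
#' kernel `exp(-gamma ||u - v||^2)`. The map is a pure function of
#' `cfg$rbf_seed`, so kernelization is deterministic.
#'
#' @param v Numeric vector of length 6, or an n x 6 matrix.
#' @param cfg A [feature_config()], or a prebuilt map from the internal
#'   constructor.
#' @return Numeric vector of length `rbf_dim` (or an n x rbf_dim matrix).
#' @export
kernelize <- function(v, cfg = feature_config()) {
  map <- if (inherits(cfg, "feature_config")) rbf_map(cfg) else cfg
  single <- is.null(dim(v))
  x <- if (single) matrix(v, 1L) else v
  stop_if(ncol(x) != nrow(map$W), "feature dimension mismatch")
  z <- sqrt(2 / map$dim) * cos(sweep(x %*% map$W, 2L, map$b, "+"))
  if (single) drop(z) else z
}
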