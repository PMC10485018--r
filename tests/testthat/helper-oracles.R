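# Independent brute-force oracles and small fixture builders. All oracles
# avoid the package's spatial-tree code paths: distances are computed
# exhaustively and sorted per pixel. Distance ties are broken by the measured
# pixel's linear (column-major) index, the same deterministic rule the
# package documents.

ms_from_indices <- function(img, idx) {
  rows <- nrow(img)
  coords <- cbind((idx - 1L) %% rows + 1L, (idx - 1L) %/% rows + 1L)
  measurement_set(coords, img[idx], dim(img))
}

ms_from_mask <- function(img, mask) ms_from_indices(img, which(mask))

random_ms <- function(rows, cols, n, seed) {
  set.seed(seed)
  img <- matrix(runif(rows * cols), rows, cols)
  ms_from_indices(img, sample(rows * cols, n))
}

# exhaustive k nearest measured points of one pixel, tie-broken by linear index
brute_knn <- function(m, pixel, k) {
  rows <- m$grid[1L]
  d <- sqrt((m$coords[, 1L] - pixel[1L])^2 + (m$coords[, 2L] - pixel[2L])^2)
  lin <- (m$coords[, 2L] - 1L) * rows + m$coords[, 1L]
  o <- order(d, lin)[seq_len(min(k, length(d)))]
  list(d = d[o], values = m$values[o], idx = o)
}

brute_idw <- function(m, k = 10L, p = 2) {
  rows <- m$grid[1L]; cols <- m$grid[2L]
  out <- matrix(NA_real_, rows, cols)
  lin <- (m$coords[, 2L] - 1L) * rows + m$coords[, 1L]
  out[lin] <- m$values
  for (i in which(is.na(out))) {
    px <- c((i - 1L) %% rows + 1L, (i - 1L) %/% rows + 1L)
    nn <- brute_knn(m, px, k)
    w <- nn$d^(-p)
    out[i] <- sum(w * nn$values) / sum(w)
  }
  out
}

# full-image RD by complete recomputation with the point added
brute_rd <- function(truth, m, pixel, k = 10L) {
  r1 <- brute_idw(m, k)
  m2 <- measurement_set(rbind(m$coords, pixel),
                        c(m$values, truth[pixel[1L], pixel[2L]]), m$grid)
  r2 <- brute_idw(m2, k)
  sum((truth - r1)^2) - sum((truth - r2)^2)
}

# feature vector of one pixel by direct enumeration
brute_features <- function(m, recon, pixel, cfg = feature_config()) {
  rows <- m$grid[1L]; cols <- m$grid[2L]
  r <- pixel[1L]; cl <- pixel[2L]
  rad <- if (!is.null(cfg$radius)) cfg$radius else
    max(1, 0.25 * sqrt(rows * cols / nrow(m$coords)))
  gx <- if (cl == 1L) recon[r, 2L] - recon[r, 1L]
        else if (cl == cols) recon[r, cols] - recon[r, cols - 1L]
        else (recon[r, cl + 1L] - recon[r, cl - 1L]) / 2
  gy <- if (r == 1L) recon[2L, cl] - recon[1L, cl]
        else if (r == rows) recon[rows, cl] - recon[rows - 1L, cl]
        else (recon[r + 1L, cl] - recon[r - 1L, cl]) / 2
  nn <- brute_knn(m, pixel, cfg$k)
  dev <- abs(nn$values - recon[r, cl])
  w <- nn$d^(-2)
  keep <- nn$d <= rad
  if (!any(keep)) keep <- rep(TRUE, length(w))
  w <- w * keep
  sigma1 <- sum(w * dev) / sum(w)
  sigma2 <- sum(w * dev^2) / sum(w)
  inside <- 0L; measured <- 0L
  mask <- matrix(FALSE, rows, cols)
  mask[(m$coords[, 2L] - 1L) * rows + m$coords[, 1L]] <- TRUE
  for (rr in seq_len(rows)) for (cc in seq_len(cols)) {
    if ((rr - r)^2 + (cc - cl)^2 <= rad^2) {
      inside <- inside + 1L
      if (mask[rr, cc]) measured <- measured + 1L
    }
  }
  c(grad_x = gx, grad_y = gy, sigma1 = sigma1, sigma2 = sigma2,
    nearest_dist = nn$d[1L], density = measured / inside)
}

# exhaustive open-path optimum over all permutations (n <= 8)
brute_route_optimum <- function(points, start) {
  n <- nrow(points)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    best <- min(best, route_length(points[p, , drop = FALSE], start))
  }
  best
}
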