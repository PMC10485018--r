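# Internal helpers shared across modules.

#' @keywords internal
stop_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

# Expand one master seed into independent per-component substreams.
# Plain affine hash kept inside 32-bit integer range.
#' @keywords internal
substream_seed <- function(seed, stream) {
  seed <- as.numeric(seed); stream <- as.numeric(stream)
  as.integer((seed * 2654435.0 + stream * 97911.0 + 12345.0) %% 2147483647)
}

# All grid pixel coordinates as an N x 2 (row, col) matrix, column-major order.
#' @keywords internal
grid_coords <- function(rows, cols) {
  cbind(rep(seq_len(rows), times = cols), rep(seq_len(cols), each = rows))
}

#' @keywords internal
coords_to_index <- function(coords, rows) {
  (coords[, 2L] - 1L) * rows + coords[, 1L]
}

#' @keywords internal
index_to_coords <- function(idx, rows) {
  cbind((idx - 1L) %% rows + 1L, (idx - 1L) %/% rows + 1L)
}

# Offsets (drow, dcol) of the pixel disc of radius r (Euclidean, inclusive).
#' @keywords internal
disc_offsets <- function(r) {
  m <- floor(r)
  d <- expand.grid(dr = -m:m, dc = -m:m)
  keep <- d$dr^2 + d$dc^2 <= r^2
  cbind(d$dr[keep], d$dc[keep])
}

# Count, for every pixel, how many TRUE cells of `mask` lie within the disc of
# radius r, and how many disc pixels fall inside the grid. Exact, via shifts.
#' @keywords internal
disc_counts <- function(mask, r) {
  rows <- nrow(mask); cols <- ncol(mask)
  offs <- disc_offsets(r)
  hits <- matrix(0L, rows, cols)
  total <- matrix(0L, rows, cols)
  mi <- matrix(as.integer(mask), rows, cols)
  for (i in seq_len(nrow(offs))) {
    dr <- offs[i, 1L]; dc <- offs[i, 2L]
    r_src <- max(1L, 1L - dr):min(rows, rows - dr)
    c_src <- max(1L, 1L - dc):min(cols, cols - dc)
    r_dst <- r_src + dr; c_dst <- c_src + dc
    hits[r_src, c_src] <- hits[r_src, c_src] + mi[r_dst, c_dst]
    total[r_src, c_src] <- total[r_src, c_src] + 1L
  }
  list(hits = hits, total = total)
}

# Local sums over w x w windows (w odd) of the "valid" region, via cumsums.
# Returns a (rows-w+1) x (cols-w+1) matrix.
#' @keywords internal
valid_window_sums <- function(x, w) {
  rows <- nrow(x); cols <- ncol(x)
  cs <- apply(apply(x, 2L, cumsum), 1L, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, rows + 1L, cols + 1L)
  pad[-1L, -1L] <- cs
  i <- seq_len(rows - w + 1L); j <- seq_len(cols - w + 1L)
  pad[i + w, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
    pad[i + w, j, drop = FALSE] + pad[i, j, drop = FALSE]
}

# Deterministic k-nearest measured neighbors for each query pixel.
# RANN's kd-tree breaks distance ties arbitrarily; on integer grids ties at
# the k-boundary are common, so the returned set is made deterministic by
# re-breaking ties lexicographically on (distance, measured-pixel linear
# index). Also reports the boundary element (the set's maximum under that
# order), which is the element displaced when a closer point is inserted.
#' @keywords internal
knn_measured <- function(meas_coords, meas_lin, query_coords, k) {
  n_meas <- nrow(meas_coords)
  nq <- nrow(query_coords)
  kk <- min(k, n_meas)
  kq <- min(kk + 16L, n_meas)
  nn <- RANN::nn2(meas_coords, query_coords, k = kq)
  d <- matrix(nn$nn.dists, nq); id <- matrix(nn$nn.idx, nq)
  if (kq > kk) {
    # one radix sort re-breaks all ties at once: order every row's
    # candidates by (distance, linear index), then keep the first kk
    o <- order(rep(seq_len(nq), times = kq), as.vector(d),
               meas_lin[as.vector(id)])
    d <- matrix(as.vector(d)[o], nq, kq, byrow = TRUE)
    id <- matrix(as.vector(id)[o], nq, kq, byrow = TRUE)
    d <- d[, seq_len(kk), drop = FALSE]
    id <- id[, seq_len(kk), drop = FALSE]
  }
  lin <- matrix(meas_lin[id], nq)
  bl <- lin
  bl[d != d[, kk]] <- -Inf
  bpos <- max.col(bl, ties.method = "last")
  ri <- seq_len(nq)
  list(d = d, idx = id, bdist = d[, kk], bpos = bpos,
       blin = bl[cbind(ri, bpos)])
}

# Otsu threshold on a numeric vector (256-bin histogram).
#' @keywords internal
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1L]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1L] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}
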