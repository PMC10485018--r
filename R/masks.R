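# Initialization and static baseline sampling patterns: 2-D Hammersley
# low-discrepancy points, equally spaced raster lattices, and uniform random
# masks.

# Base-2 van der Corput radical inverse of integers i (vectorized).
#' @keywords internal
van_der_corput2 <- function(i) {
  out <- numeric(length(i))
  f <- 0.5
  while (any(i > 0L)) {
    out <- out + f * (i %% 2L)
    i <- i %/% 2L
    f <- f / 2
  }
  out
}

#' Hammersley sample points on a scan grid
#'
#' Deterministic low-discrepancy point set: coordinate one is `i/n`, the other
#' the base-2 van der Corput radical inverse, scaled to the grid. After
#' rounding to pixels, duplicates are discarded and the sequence regenerated
#' at a larger length until the requested count of distinct pixels is met.
#'
#' @param grid Length-2 (rows, cols).
#' @param fraction Fraction of the grid to cover, in (0, 1]. A fraction that
#'   would round to 0 points is promoted to a single point.
#' @return Integer matrix (n x 2) of distinct (row, col) pixels,
#'   n = `round(fraction * rows * cols)` (at least 1).
#' @export
hammersley_points <- function(grid, fraction) {
  rows <- as.integer(grid[1L]); cols <- as.integer(grid[2L])
  stop_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]")
  N <- rows * cols
  target <- max(1L, round(fraction * N))
  n_try <- target
  repeat {
    i <- seq_len(n_try)
    u <- (i - 0.5) / n_try          # stratified axis
    v <- van_der_corput2(i)         # radical-inverse axis
    r <- pmin(rows, 1L + floor(u * rows))
    cl <- pmin(cols, 1L + floor(v * cols))
    idx <- (cl - 1L) * rows + r
    keep <- !duplicated(idx)
    if (sum(keep) >= target) {
      coords <- cbind(r[keep], cl[keep])[seq_len(target), , drop = FALSE]
      storage.mode(coords) <- "integer"
      return(coords)
    }
    n_try <- max(n_try + 1L, ceiling(n_try * 1.5))
  }
}

#' Static sampling masks
#'
#' Boolean grid masks with exactly `n` measured cells:
#' `raster_mask` builds the aspect-ratio-preserving equally spaced lattice
#' nearest to `n` points (per-axis strides around `sqrt(N/n)`, trimmed to hit
#' `n` exactly); `uniform_random_mask` samples without replacement;
#' `ldr_mask` takes the first `n` Hammersley points (low-discrepancy random).
#'
#' @param grid Length-2 (rows, cols).
#' @param n Number of measured cells, `1 <= n <= rows * cols`.
#' @param seed Seed for the uniform random mask.
#' @return Logical matrix with exactly `n` `TRUE` cells.
#' @export
raster_mask <- function(grid, n) {
  rows <- as.integer(grid[1L]); cols <- as.integer(grid[2L])
  N <- rows * cols
  stop_if(n < 1 || n > N, "n out of range")
  mask <- matrix(FALSE, rows, cols)
  if (n == N) { mask[] <- TRUE; return(mask) }
  # per-axis point counts near the aspect-preserving ideal (stride ~ sqrt(N/n)
  # scaled per axis), then centered lattice positions with equal strides
  nr <- max(1L, min(rows, round(sqrt(n * rows / cols))))
  nc <- max(1L, min(cols, ceiling(n / nr)))
  while (nr * nc < n) {
    if (nr < rows) nr <- nr + 1L else nc <- nc + 1L
  }
  rr <- ceiling((seq_len(nr) - 0.5) * rows / nr)
  cc <- ceiling((seq_len(nc) - 0.5) * cols / nc)
  lattice <- cbind(r = rep(rr, times = nc), c = rep(cc, each = nr))
  surplus <- nrow(lattice) - n
  if (surplus > 0L) {
    # trim surplus points evenly across the lattice
    drop_idx <- unique(round(seq(1L, nrow(lattice), length.out = surplus)))
    extra <- surplus - length(drop_idx)
    if (extra > 0L) {
      drop_idx <- c(drop_idx,
                    utils::tail(setdiff(seq_len(nrow(lattice)), drop_idx),
                                extra))
    }
    lattice <- lattice[-drop_idx, , drop = FALSE]
  }
  mask[lattice] <- TRUE
  mask
}

#' @rdname raster_mask
#' @export
uniform_random_mask <- function(grid, n, seed = 1L) {
  rows <- as.integer(grid[1L]); cols <- as.integer(grid[2L])
  N <- rows * cols
  stop_if(n < 1 || n > N, "n out of range")
  mask <- matrix(FALSE, rows, cols)
  idx <- with_seed(seed, sample.int(N, n))
  mask[idx] <- TRUE
  mask
}

#' @rdname raster_mask
#' @export
ldr_mask <- function(grid, n) {
  rows <- as.integer(grid[1L]); cols <- as.integer(grid[2L])
  N <- rows * cols
  stop_if(n < 1 || n > N, "n out of range")
  pts <- hammersley_points(grid, n / N)
  if (nrow(pts) > n) pts <- pts[seq_len(n), , drop = FALSE]
  mask <- matrix(FALSE, rows, cols)
  mask[pts] <- TRUE
  mask
}

# Measurement set from a boolean mask on a ground-truth image.
#' @keywords internal
mask_to_measurements <- function(sample, mask, noise = noise_model("none")) {
  idx <- which(mask)
  coords <- index_to_coords(idx, nrow(sample))
  measurement_set(coords, measure_points(sample, coords, noise),
                  dim(sample))
}
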