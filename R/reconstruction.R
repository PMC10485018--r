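# Sparse-measurement containers and reconstruction: fast IDW interpolation
# for the in-loop estimate and variational biharmonic inpainting for final
# images.

#' Measurement set
#'
#' Ordered history of point measurements on a scan grid: the k x 2 record of
#' (location, value) pairs that the decision engine conditions on.
#'
#' @param coords Integer matrix (k x 2) of (row, col) locations, 1-based,
#'   in acquisition order.
#' @param values Numeric vector of measured values (>= 0), same length.
#' @param grid_shape Length-2 integer vector (rows, cols).
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(coords, values, grid_shape) {
  coords <- matrix(as.integer(coords), ncol = 2L)
  values <- as.numeric(values)
  stop_if(nrow(coords) != length(values),
          "coords and values lengths differ")
  stop_if(length(grid_shape) != 2L || any(grid_shape < 1),
          "grid_shape must be (rows, cols)")
  rows <- as.integer(grid_shape[1L]); cols <- as.integer(grid_shape[2L])
  stop_if(any(coords[, 1L] < 1L | coords[, 1L] > rows |
                coords[, 2L] < 1L | coords[, 2L] > cols),
          "measurement location outside the grid")
  idx <- coords_to_index(coords, rows)
  stop_if(anyDuplicated(idx) > 0L, "duplicate measurement locations")
  structure(list(coords = coords, values = values,
                 grid = c(rows, cols)),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d points on a %d x %d grid (%.2f%% coverage)\n",
              nrow(x$coords), x$grid[1L], x$grid[2L],
              100 * nrow(x$coords) / prod(x$grid)))
  invisible(x)
}

#' @export
length.measurement_set <- function(x) nrow(x$coords)

# Boolean measured mask.
#' @keywords internal
ms_mask <- function(m) {
  mask <- matrix(FALSE, m$grid[1L], m$grid[2L])
  mask[coords_to_index(m$coords, m$grid[1L])] <- TRUE
  mask
}

# Append measurements (no duplicate checking beyond the constructor's).
#' @keywords internal
ms_add <- function(m, coords, values) {
  measurement_set(rbind(m$coords, matrix(as.integer(coords), ncol = 2L)),
                  c(m$values, values), m$grid)
}

# Core IDW evaluation: for each query point, inverse-distance-weighted mean of
# the k nearest measured values (deterministic tie-broken kd-tree search).
#' @keywords internal
idw_values <- function(meas_coords, meas_values, query_coords, n_neighbors,
                       power, grid_rows) {
  meas_lin <- coords_to_index(meas_coords, grid_rows)
  nn <- knn_measured(meas_coords, meas_lin, query_coords, n_neighbors)
  vals <- matrix(meas_values[nn$idx], nrow = nrow(query_coords))
  if (ncol(vals) == 1L) return(vals[, 1L])   # single neighbor: weight cancels
  w <- nn$d^(-power)
  est <- rowSums(w * vals) / rowSums(w)
  exact <- nn$d[, 1L] == 0
  if (any(exact)) {
    est[exact] <- vals[exact, 1L]
  }
  est
}

#' Inverse-distance-weighted reconstruction
#'
#' Estimates the full image from a sparse measurement set by Shepard
#' interpolation: each unmeasured pixel is the inverse-distance-weighted mean
#' of its `n_neighbors` nearest measured values (weights d^-power). Measured
#' pixels pass through exactly. Neighbor search uses a k-d tree.
#'
#' @param m A [measurement_set()] (nonempty).
#' @param n_neighbors Number of nearest measured points used per pixel
#'   (default 10). Use `Inf` (or `all_points = TRUE`) for full-set IDW.
#' @param power Inverse-distance exponent (default 2, the Shepard choice).
#' @param all_points If TRUE, use every measured point for every pixel.
#' @return Numeric matrix of the grid shape, attribute `method = "idw"`.
#' @export
idw_reconstruct <- function(m, n_neighbors = 10L, power = 2,
                            all_points = FALSE) {
  stopifnot(inherits(m, "measurement_set"))
  stop_if(nrow(m$coords) == 0L, "cannot reconstruct from an empty measurement set")
  rows <- m$grid[1L]; cols <- m$grid[2L]
  k <- if (all_points || is.infinite(n_neighbors)) nrow(m$coords)
       else n_neighbors
  out <- matrix(NA_real_, rows, cols)
  midx <- coords_to_index(m$coords, rows)
  out[midx] <- m$values
  un <- which(is.na(out))
  if (length(un)) {
    qc <- index_to_coords(un, rows)
    out[un] <- idw_values(m$coords, m$values, qc, k, power, rows)
  }
  attr(out, "method") <- "idw"
  out
}

# Discrete thin-plate (bilaplacian) energy operator B = Dxx'Dxx + 2 Dxy'Dxy +
# Dyy'Dyy over an rows x cols grid, using second differences where defined.
# Null space = affine images, so harmonic ramps inpaint exactly.
#' @keywords internal
thin_plate_operator <- function(rows, cols) {
  N <- rows * cols
  ix <- function(r, c) (c - 1L) * rows + r
  tri <- function(i, j, x) Matrix::sparseMatrix(i = i, j = j, x = x,
                                                dims = c(max(i), N))
  # Dyy: vertical second difference (along rows)
  n1 <- (rows - 2L) * cols
  if (n1 > 0L) {
    r <- rep(2:(rows - 1L), times = cols)
    c <- rep(seq_len(cols), each = rows - 2L)
    rid <- seq_len(n1)
    Dyy <- Matrix::sparseMatrix(
      i = rep(rid, 3L),
      j = c(ix(r - 1L, c), ix(r, c), ix(r + 1L, c)),
      x = rep(c(1, -2, 1), each = n1), dims = c(n1, N))
  } else Dyy <- NULL
  n2 <- rows * (cols - 2L)
  if (n2 > 0L) {
    r <- rep(seq_len(rows), times = cols - 2L)
    c <- rep(2:(cols - 1L), each = rows)
    rid <- seq_len(n2)
    Dxx <- Matrix::sparseMatrix(
      i = rep(rid, 3L),
      j = c(ix(r, c - 1L), ix(r, c), ix(r, c + 1L)),
      x = rep(c(1, -2, 1), each = n2), dims = c(n2, N))
  } else Dxx <- NULL
  n3 <- (rows - 1L) * (cols - 1L)
  if (n3 > 0L) {
    r <- rep(seq_len(rows - 1L), times = cols - 1L)
    c <- rep(seq_len(cols - 1L), each = rows - 1L)
    rid <- seq_len(n3)
    Dxy <- Matrix::sparseMatrix(
      i = rep(rid, 4L),
      j = c(ix(r, c), ix(r + 1L, c), ix(r, c + 1L), ix(r + 1L, c + 1L)),
      x = rep(c(1, -1, -1, 1), each = n3), dims = c(n3, N))
  } else Dxy <- NULL
  B <- Matrix::Matrix(0, N, N, sparse = TRUE)
  if (!is.null(Dxx)) B <- B + Matrix::crossprod(Dxx)
  if (!is.null(Dyy)) B <- B + Matrix::crossprod(Dyy)
  if (!is.null(Dxy)) B <- B + 2 * Matrix::crossprod(Dxy)
  B
}

#' Biharmonic inpainting of a sparse measurement set
#'
#' Fills unmeasured pixels with the image of minimal discrete thin-plate
#' (squared second-derivative) energy subject to exact interpolation of the
#' measured values — the variational form of biharmonic inpainting. Measured
#' pixels pass through exactly; used for final, higher-quality images.
#'
#' @param m A [measurement_set()] (nonempty).
#' @return Numeric matrix of the grid shape, attribute `method = "biharmonic"`.
#' @export
biharmonic_inpaint <- function(m) {
  stopifnot(inherits(m, "measurement_set"))
  stop_if(nrow(m$coords) == 0L, "cannot inpaint from an empty measurement set")
  rows <- m$grid[1L]; cols <- m$grid[2L]
  N <- rows * cols
  out <- matrix(NA_real_, rows, cols)
  midx <- coords_to_index(m$coords, rows)
  out[midx] <- m$values
  un <- which(is.na(out))
  if (length(un) == 0L) {
    attr(out, "method") <- "biharmonic"
    return(out)
  }
  if (nrow(m$coords) < 3L) {
    # too few constraints to pin the affine null space: fall back to the
    # IDW estimate (constant for a single point)
    out[un] <- idw_values(m$coords, m$values, index_to_coords(un, rows),
                          nrow(m$coords), 2, rows)
    attr(out, "method") <- "biharmonic"
    return(out)
  }
  B <- thin_plate_operator(rows, cols)
  rhs <- -(B[un, midx, drop = FALSE] %*% m$values)
  Buu <- B[un, un, drop = FALSE]
  sol <- tryCatch(
    Matrix::solve(Buu, rhs),
    error = function(e)
      Matrix::solve(Buu + 1e-9 * Matrix::Diagonal(length(un)), rhs))
  out[un] <- as.numeric(sol)
  attr(out, "method") <- "biharmonic"
  out
}
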