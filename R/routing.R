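# Scan-route optimization: order each batch of candidate points into a short
# open travel path for the scan motors (nearest-neighbor construction +
# 2-opt improvement; n is small, a batch is typically 50 points).

#' Total length of a scan path
#'
#' Sum of Euclidean legs from `start` through `points_in_order`.
#'
#' @param points_in_order Numeric matrix (n x 2) of (row, col) points.
#' @param start Length-2 starting position.
#' @return Non-negative scalar; 0 iff the path is a single point at `start`.
#' @export
route_length <- function(points_in_order, start) {
  if (is.null(points_in_order) || NROW(points_in_order) == 0L) return(0)
  p <- rbind(as.numeric(start), matrix(points_in_order, ncol = 2L))
  sum(sqrt(rowSums(diff(p)^2)))
}

# Length of an order (indices into pts) given a start-distance vector and a
# full pairwise distance matrix.
#' @keywords internal
order_length <- function(ord, d_start, D) {
  n <- length(ord)
  L <- d_start[ord[1L]]
  if (n > 1L) L <- L + sum(D[cbind(ord[-n], ord[-1L])])
  L
}

# 2-opt (segment reversal) + or-opt (relocation of 1-3 consecutive points)
# local improvement of an open path; first-improvement sweeps until neither
# move type improves. Deterministic.
#' @keywords internal
two_opt <- function(ord, d_start, D) {
  n <- length(ord)
  if (n < 3L) return(ord)
  leg <- function(a, b) if (a == 0L) d_start[b] else D[a, b]
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    # 2-opt: reverse ord[i..j]
    for (i in seq_len(n - 1L)) {
      pred <- if (i == 1L) 0L else ord[i - 1L]
      for (j in (i + 1L):n) {
        old <- leg(pred, ord[i]) + (if (j < n) D[ord[j], ord[j + 1L]] else 0)
        new <- leg(pred, ord[j]) + (if (j < n) D[ord[i], ord[j + 1L]] else 0)
        if (new < old - 1e-12) {
          ord[i:j] <- ord[j:i]
          improved <- TRUE
        }
      }
    }
    # or-opt: move a segment of length 1..3 elsewhere
    for (seg_len in 1:3) {
      if (n <= seg_len) next
      i <- 1L
      while (i + seg_len - 1L <= n) {
        j <- i + seg_len - 1L
        pred <- if (i == 1L) 0L else ord[i - 1L]
        succ <- if (j < n) ord[j + 1L] else 0L
        gain_remove <- leg(pred, ord[i]) +
          (if (succ != 0L) D[ord[j], succ] else 0) -
          (if (succ != 0L) leg(pred, succ) else 0)
        rest <- ord[-(i:j)]
        m <- length(rest)
        moved <- FALSE
        for (pos in 0:m) {          # insert segment after rest[pos]
          if (pos == i - 1L) next   # original position
          a <- if (pos == 0L) 0L else rest[pos]
          b <- if (pos < m) rest[pos + 1L] else 0L
          add <- leg(a, ord[i]) + (if (b != 0L) D[ord[j], b] else 0) -
            (if (b != 0L) leg(a, b) else 0)
          if (add < gain_remove - 1e-12) {
            seg <- ord[i:j]
            ord <- append(rest, seg, after = pos)
            improved <- TRUE
            moved <- TRUE
            break
          }
        }
        if (!moved) i <- i + 1L
      }
    }
  }
  ord
}

#' Optimize the visiting order of a measurement batch
#'
#' Builds a short open path (no return to start) through all points: takes
#' the better of the input order and a greedy nearest-neighbor construction
#' from `start`, then applies 2-opt segment reversals and or-opt segment
#' relocations to local optimality. The result is never longer than the
#' input order and is a permutation of the input points. Deterministic.
#'
#' @param points Numeric matrix (n x 2) of distinct (row, col) points.
#' @param start Length-2 starting position (typically the previous batch's
#'   final point).
#' @return An object of class `scan_route`: list with `points` (n x 2 in
#'   visit order), `start`, and `total_length`.
#' @export
optimize_route <- function(points, start) {
  pts <- matrix(points, ncol = 2L)
  n <- nrow(pts)
  stop_if(n == 0L, "empty point set")
  stop_if(anyDuplicated(pts) > 0L, "duplicate points in batch")
  d_start <- sqrt((pts[, 1L] - start[1L])^2 + (pts[, 2L] - start[2L])^2)
  if (n == 1L) {
    return(structure(list(points = pts, start = as.numeric(start),
                          total_length = d_start),
                     class = "scan_route"))
  }
  D <- as.matrix(stats::dist(pts))
  # greedy nearest-neighbor order from the start point
  nn_ord <- integer(n)
  remaining <- seq_len(n)
  cur_d <- d_start
  for (i in seq_len(n)) {
    pick <- remaining[which.min(cur_d[remaining])]
    nn_ord[i] <- pick
    remaining <- remaining[remaining != pick]
    cur_d <- D[pick, ]
  }
  input_ord <- seq_len(n)
  seed_ord <- if (order_length(input_ord, d_start, D) <=
                    order_length(nn_ord, d_start, D)) input_ord else nn_ord
  ord <- two_opt(seed_ord, d_start, D)
  if (order_length(ord, d_start, D) >
        order_length(input_ord, d_start, D) + 1e-12) {
    ord <- input_ord   # safety net: never worse than the input order
  }
  structure(list(points = pts[ord, , drop = FALSE],
                 start = as.numeric(start),
                 total_length = order_length(ord, d_start, D)),
            class = "scan_route")
}

#' @export
print.scan_route <- function(x, ...) {
  cat(sprintf("<scan_route> %d points, length %.3f px from (%g, %g)\n",
              nrow(x$points), x$total_length, x$start[1L], x$start[2L]))
  invisible(x)
}
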