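# The closed acquisition loop: low-discrepancy initialization, ERD-guided
# batch selection, route-optimized simulated measurement, per-iteration
# bookkeeping and stopping.

#' Stopping rule for the acquisition loop
#'
#' `coverage_only` stops at the configured maximum coverage. `erd_plateau`
#' additionally stops once the relative change of the summed ERD over the
#' last `window` iterations falls below `rel_tolerance` — a numerical
#' operationalization of watching the ERD stabilize.
#'
#' @param kind `"coverage_only"` or `"erd_plateau"`.
#' @param window Number of trailing iterations examined (>= 2).
#' @param rel_tolerance Relative-change threshold (> 0).
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(kind = c("coverage_only", "erd_plateau"),
                          window = 5L, rel_tolerance = 0.02) {
  kind <- match.arg(kind)
  stop_if(window < 2, "window must be >= 2")
  stop_if(rel_tolerance <= 0, "rel_tolerance must be > 0")
  structure(list(kind = kind, window = as.integer(window),
                 rel_tolerance = as.numeric(rel_tolerance)),
            class = "stopping_rule")
}

#' Acquisition-loop configuration
#'
#' @param initial_fraction Coverage of the low-discrepancy initialization
#'   (default 0.01: one percent of the grid).
#' @param batch_size Points measured per iteration (default 50, which keeps
#'   per-batch decision overhead negligible).
#' @param max_coverage Coverage at which the scan always stops (default 0.35).
#' @param stopping A [stopping_rule()].
#' @param checkpoint_coverages Coverage fractions at which a snapshot of the
#'   measurement set is stored in the trajectory (for later biharmonic
#'   inpainting / comparison).
#' @param seed Master seed for measurement noise.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(initial_fraction = 0.01, batch_size = 50L,
                        max_coverage = 0.35,
                        stopping = stopping_rule("coverage_only"),
                        checkpoint_coverages = numeric(0),
                        seed = 1L) {
  stop_if(initial_fraction <= 0 || initial_fraction >= max_coverage,
          "need 0 < initial_fraction < max_coverage")
  stop_if(max_coverage > 1, "max_coverage must be <= 1")
  stop_if(batch_size < 1, "batch_size must be >= 1")
  stopifnot(inherits(stopping, "stopping_rule"))
  structure(list(initial_fraction = as.numeric(initial_fraction),
                 batch_size = as.integer(batch_size),
                 max_coverage = as.numeric(max_coverage),
                 stopping = stopping,
                 checkpoint_coverages = as.numeric(checkpoint_coverages),
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Select the highest-ERD batch of pixels
#'
#' Returns up to `batch_size` unmeasured pixels with the largest ERD values,
#' in descending ERD order; ties broken lexicographically by (row, col).
#'
#' @param erd ERD map matrix (`NA` at measured pixels).
#' @param batch_size Maximum batch size.
#' @return Integer matrix (m x 2) of (row, col), m = min(batch_size,
#'   number of unmeasured pixels).
#' @export
select_batch <- function(erd, batch_size) {
  un <- which(!is.na(erd))
  stop_if(length(un) == 0L, "ERD map has no defined pixels")
  rows <- nrow(erd)
  coords <- index_to_coords(un, rows)
  ord <- order(-erd[un], coords[, 1L], coords[, 2L])
  take <- ord[seq_len(min(batch_size, length(un)))]
  out <- coords[take, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Check the stopping rule against a trajectory
#'
#' @param traj A `fast_scan` trajectory (or its `$iterations` data frame).
#' @param rule A [stopping_rule()].
#' @param max_coverage Coverage ceiling used by `coverage_only`.
#' @return `TRUE` if the scan should stop.
#' @export
check_stopping <- function(traj, rule, max_coverage = 1) {
  it <- if (is.data.frame(traj)) traj else traj$iterations
  if (nrow(it) == 0L) return(FALSE)
  cov_now <- it$coverage[nrow(it)]
  if (cov_now >= max_coverage) return(TRUE)
  if (rule$kind == "coverage_only") return(FALSE)
  w <- rule$window
  if (nrow(it) < w) return(FALSE)
  e <- utils::tail(it$total_erd, w)
  denom <- max(abs(e))
  if (denom == 0) return(TRUE)
  (max(e) - min(e)) / denom < rule$rel_tolerance
}

#' Run the autonomous adaptive scan
#'
#' The closed loop: measure a Hammersley initialization, then repeat
#' {IDW reconstruction -> ERD prediction -> top-ERD batch selection ->
#' route optimization -> simulated measurement} until the stopping rule or
#' the coverage ceiling is hit. Per-iteration metrics are recorded against
#' the ground truth, and a final biharmonic reconstruction is computed once
#' at the end.
#'
#' @param sample Ground-truth image matrix (the simulated subject).
#' @param model A trained [train_erd_model()] decision model.
#' @param cfg A [scan_config()].
#' @param noise A [noise_model()] applied to every simulated measurement.
#' @param feature_cfg Feature configuration; defaults to the model's.
#' @param verbose Print one line per iteration.
#' @return An object of class `fast_scan`: list with `iterations` (data frame
#'   of iteration, n_measured, coverage, nrmse, ssim, total_erd,
#'   route_length, route_length_input — the length the unoptimized
#'   ERD-descending order would have travelled), `measurements` (final
#'   [measurement_set()]), `batches`
#'   (list of visit-ordered batch matrices), `checkpoints` (named list of
#'   measurement-set snapshots), `final_idw`, `final_biharmonic`, and `config`.
#' @export
run_fast_scan <- function(sample, model, cfg = scan_config(),
                          noise = noise_model("none"),
                          feature_cfg = model$cfg, verbose = FALSE) {
  stopifnot(inherits(model, "erd_model"), inherits(cfg, "scan_config"))
  rows <- nrow(sample); cols <- ncol(sample)
  N <- rows * cols
  target_n <- round(cfg$max_coverage * N)
  init <- hammersley_points(c(rows, cols), cfg$initial_fraction)
  noise_stream <- 0L
  measure_seeded <- function(coords) {
    noise_stream <<- noise_stream + 1L
    if (noise$kind == "none") {
      measure_points(sample, coords, noise)
    } else {
      with_seed(substream_seed(cfg$seed, noise_stream),
                measure_points(sample, coords, noise))
    }
  }
  m <- measurement_set(init, measure_seeded(init), c(rows, cols))
  checkpoints <- list()
  pending_cp <- sort(cfg$checkpoint_coverages)
  record_checkpoints <- function() {
    while (length(pending_cp) &&
             nrow(m$coords) >= round(pending_cp[1L] * N)) {
      checkpoints[[sprintf("%g", pending_cp[1L])]] <<- m
      pending_cp <<- pending_cp[-1L]
    }
  }
  record_checkpoints()
  batches <- list()
  rec <- list()
  iter <- 0L
  last_point <- init[nrow(init), ]
  recon <- idw_reconstruct(m, n_neighbors = feature_cfg$k)
  repeat {
    n_meas <- nrow(m$coords)
    if (n_meas >= target_n || n_meas >= N) break
    erd <- predict_erd(model, m, recon, feature_cfg)
    iter <- iter + 1L
    batch <- select_batch(erd, min(cfg$batch_size, target_n - n_meas))
    input_length <- route_length(batch, last_point)
    route <- optimize_route(batch, last_point)
    vals <- measure_seeded(route$points)
    m <- ms_add(m, route$points, vals)
    record_checkpoints()
    last_point <- route$points[nrow(route$points), ]
    batches[[iter]] <- route$points
    recon <- idw_reconstruct(m, n_neighbors = feature_cfg$k)
    rec[[iter]] <- data.frame(
      iteration = iter,
      n_measured = nrow(m$coords),
      coverage = nrow(m$coords) / N,
      nrmse = nrmse(sample, recon),
      ssim = ssim(sample, recon),
      total_erd = sum(erd, na.rm = TRUE),
      route_length = route$total_length,
      route_length_input = input_length)
    if (verbose) {
      with(rec[[iter]], cat(sprintf(
        "iter %3d  coverage %5.1f%%  nrmse %.4f  ssim %.4f  ERD %.3g  route %.1f\n",
        iteration, 100 * coverage, nrmse, ssim, total_erd, route_length)))
    }
    it_df <- do.call(rbind, rec)
    if (check_stopping(it_df, cfg$stopping, cfg$max_coverage)) break
  }
  iterations <- if (length(rec)) do.call(rbind, rec) else
    data.frame(iteration = integer(0), n_measured = integer(0),
               coverage = numeric(0), nrmse = numeric(0), ssim = numeric(0),
               total_erd = numeric(0), route_length = numeric(0),
               route_length_input = numeric(0))
  final_idw <- idw_reconstruct(m, n_neighbors = feature_cfg$k)
  structure(list(iterations = iterations, measurements = m,
                 batches = batches, checkpoints = checkpoints,
                 final_idw = final_idw,
                 final_biharmonic = biharmonic_inpaint(m),
                 sample_shape = c(rows, cols), config = cfg),
            class = "fast_scan")
}

#' @export
print.fast_scan <- function(x, ...) {
  n <- nrow(x$measurements$coords)
  cat(sprintf("<fast_scan> %d iterations, %d points (%.1f%% of %d x %d grid)\n",
              nrow(x$iterations), n,
              100 * n / prod(x$sample_shape),
              x$sample_shape[1L], x$sample_shape[2L]))
  if (nrow(x$iterations)) {
    last <- x$iterations[nrow(x$iterations), ]
    cat(sprintf("  final in-loop metrics: nrmse %.4f, ssim %.4f\n",
                last$nrmse, last$ssim))
  }
  invisible(x)
}

#' @export
summary.fast_scan <- function(object, ...) {
  out <- list(iterations = nrow(object$iterations),
              n_measured = nrow(object$measurements$coords),
              coverage = nrow(object$measurements$coords) /
                prod(object$sample_shape),
              metrics = object$iterations[, c("coverage", "nrmse", "ssim")])
  class(out) <- "summary.fast_scan"
  out
}

#' @export
print.summary.fast_scan <- function(x, ...) {
  cat(sprintf("Adaptive scan: %d iterations to %.1f%% coverage (%d points)\n",
              x$iterations, 100 * x$coverage, x$n_measured))
  if (nrow(x$metrics)) {
    sel <- unique(round(seq(1L, nrow(x$metrics), length.out = 6L)))
    print(x$metrics[sel, ], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
plot.fast_scan <- function(x, which = c("metrics", "points"), ...) {
  which <- match.arg(which)
  if (which == "metrics" && nrow(x$iterations)) {
    old <- graphics::par(mfrow = c(1L, 2L)); on.exit(graphics::par(old))
    graphics::plot(x$iterations$coverage, x$iterations$nrmse, type = "l",
                   xlab = "coverage", ylab = "NRMSE", ...)
    graphics::plot(x$iterations$coverage, x$iterations$ssim, type = "l",
                   xlab = "coverage", ylab = "SSIM", ...)
  } else if (which == "points") {
    graphics::plot(x$measurements$coords[, 2L],
                   -x$measurements$coords[, 1L], pch = ".",
                   xlab = "col", ylab = "-row", asp = 1, ...)
  }
  invisible(x)
}
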