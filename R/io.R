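# Readers and writers tying the modules into reproducible runs: float TIFF
# images and masks, scan-log / metrics / route CSVs, diffraction-stack HDF5,
# and the run manifest.

#' Write / read a floating-point image as TIFF
#'
#' Images are stored as 32-bit float TIFF. Values outside [0, 1] (e.g. CoM
#' shift maps) are affinely rescaled for storage, with the original range
#' recorded in a JSON sidecar (`<path>.json`) and inverted on read.
#'
#' @param img Numeric matrix.
#' @param path File path.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns the numeric matrix.
#' @export
write_image_tiff <- function(img, path) {
  lo <- min(img); hi <- max(img)
  sidecar <- paste0(path, ".json")
  if (lo >= 0 && hi <= 1) {
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
    if (file.exists(sidecar)) unlink(sidecar)
  } else {
    span <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((img - lo) / span, path, bits.per.sample = 32L)
    writeLines(jsonlite::toJSON(list(rescaled = TRUE, offset = lo,
                                     span = span),
                                auto_unbox = TRUE, digits = NA), sidecar)
  }
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  out <- matrix(as.numeric(img), nrow(img), ncol(img))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(readLines(sidecar, warn = FALSE))
    if (isTRUE(meta$rescaled)) out <- out * meta$span + meta$offset
  }
  out
}

#' Write / read a boolean sampling mask as TIFF
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  matrix(img > 0.5, nrow(img), ncol(img))
}

#' Write a [0,1] image as 8-bit PNG (for documentation figures)
#'
#' @param img Numeric matrix in [0, 1].
#' @param path File path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# ---- diffraction stack HDF5 -------------------------------------------------

#' Write / read a diffraction stack as HDF5
#'
#' Layout: `/patterns` (4-D array), `/nominal_center`, `/meta` (JSON-encoded
#' generating configuration). Requires the rhdf5 package.
#'
#' @param stack A [generate_diffraction_stack()] result.
#' @param path File path.
#' @export
write_diffraction_stack <- function(stack, path) {
  stop_if(!requireNamespace("rhdf5", quietly = TRUE),
          "the rhdf5 package is required for HDF5 stack I/O")
  stopifnot(inherits(stack, "diffraction_stack"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(stack$patterns, path, "patterns")
  rhdf5::h5write(stack$nominal_center, path, "nominal_center")
  rhdf5::h5write(as.character(jsonlite::toJSON(unclass(stack$config),
                                               auto_unbox = TRUE,
                                               digits = NA)),
                 path, "meta")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_diffraction_stack
#' @export
read_diffraction_stack <- function(path) {
  stop_if(!requireNamespace("rhdf5", quietly = TRUE),
          "the rhdf5 package is required for HDF5 stack I/O")
  patterns <- rhdf5::h5read(path, "patterns")
  center <- as.numeric(rhdf5::h5read(path, "nominal_center"))
  meta <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta")))
  rhdf5::h5closeAll()
  cfg <- simulator_config(rows = meta$rows, cols = meta$cols,
                          n_flakes = meta$n_flakes,
                          thickness_levels = meta$thickness_levels,
                          n_bubbles_per_flake = meta$n_bubbles_per_flake,
                          bubble_radius_range = meta$bubble_radius_range,
                          rim_contrast = meta$rim_contrast,
                          background_level = meta$background_level,
                          flake_area_fraction = meta$flake_area_fraction,
                          seed = meta$seed)
  structure(list(patterns = patterns, nominal_center = center, config = cfg,
                 det_shape = dim(patterns)[3:4]),
            class = "diffraction_stack")
}

# ---- CSV logs ---------------------------------------------------------------

#' Write / read the scan log
#'
#' One row per measured point in acquisition order, with columns
#' `iteration` (0 for the initialization), `point_index_in_batch`, `row`,
#' `col`, `measured_value`, `cumulative_coverage`. Reading the log
#' reconstructs the measurement set exactly (locations, values, order).
#'
#' @param traj A `fast_scan` trajectory.
#' @param path File path.
#' @export
write_scan_log <- function(traj, path) {
  stopifnot(inherits(traj, "fast_scan"))
  m <- traj$measurements
  n <- nrow(m$coords)
  N <- prod(m$grid)
  batch_sizes <- vapply(traj$batches, nrow, integer(1L))
  n_init <- n - sum(batch_sizes)
  iter <- c(rep(0L, n_init),
            rep(seq_along(traj$batches), times = batch_sizes))
  in_batch <- c(seq_len(n_init),
                unlist(lapply(batch_sizes, seq_len), use.names = FALSE))
  df <- data.frame(iteration = iter, point_index_in_batch = in_batch,
                   row = m$coords[, 1L], col = m$coords[, 2L],
                   measured_value = m$values,
                   cumulative_coverage = seq_len(n) / N)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scan_log
#' @param grid_shape (rows, cols) of the scan grid.
#' @export
read_scan_log <- function(path, grid_shape) {
  df <- utils::read.csv(path)
  measurement_set(cbind(df$row, df$col), df$measured_value, grid_shape)
}

#' Write the per-iteration metrics table
#'
#' Columns: iteration, n_measured, coverage, nrmse, ssim, total_erd,
#' route_length (one row per acquisition-loop iteration).
#'
#' @param traj A `fast_scan` trajectory.
#' @param path File path.
#' @export
write_metrics_csv <- function(traj, path) {
  utils::write.csv(traj$iterations, path, row.names = FALSE)
  invisible(path)
}

#' Export a route as CSV
#'
#' Columns: visit_order, row, col, cumulative_length.
#'
#' @param route A [optimize_route()] result.
#' @param path File path.
#' @export
write_route_csv <- function(route, path) {
  stopifnot(inherits(route, "scan_route"))
  p <- rbind(route$start, route$points)
  legs <- sqrt(rowSums(diff(p)^2))
  df <- data.frame(visit_order = seq_len(nrow(route$points)),
                   row = route$points[, 1L], col = route$points[, 2L],
                   cumulative_length = cumsum(legs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export CoM maps as CSV
#'
#' Columns: row, col, comx, comy, valid (sparse per-pixel values).
#'
#' @param maps A [com_maps_from_scan()] result.
#' @param path File path.
#' @export
write_com_csv <- function(maps, path) {
  stopifnot(inherits(maps, "com_maps"))
  rows <- nrow(maps$sparse$comx)
  idx <- seq_len(length(maps$sparse$comx))
  coords <- index_to_coords(idx, rows)
  df <- data.frame(row = coords[, 1L], col = coords[, 2L],
                   comx = as.numeric(maps$sparse$comx),
                   comy = as.numeric(maps$sparse$comy),
                   valid = as.logical(maps$sparse$valid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- run manifest -----------------------------------------------------------

#' Write all outputs of a run and its manifest
#'
#' Emits the scan log, metrics CSV, measured-pixel mask, IDW and biharmonic
#' reconstruction TIFFs, optional CoM maps (TIFF + CSV), and a JSON manifest
#' listing every file with the config snapshot, seeds, toolkit version and
#' timestamps. A failure during writing leaves the manifest on disk marked
#' incomplete.
#'
#' @param traj A `fast_scan` trajectory.
#' @param outdir Output directory (created if needed).
#' @param maps Optional [com_maps_from_scan()] result.
#' @param config_text Optional config snapshot (character; stored verbatim).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(traj, outdir, maps = NULL, config_text = NULL) {
  stopifnot(inherits(traj, "fast_scan"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    toolkit = "sladscan",
    version = as.character(utils::packageVersion("sladscan")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = list(scan = traj$config$seed),
    config_snapshot = config_text,
    files = character(0),
    complete = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    manifest$files <<- c(manifest$files, name)
  }
  ok <- tryCatch({
    emit("scan_log.csv", function(p) write_scan_log(traj, p))
    emit("metrics.csv", function(p) write_metrics_csv(traj, p))
    emit("mask.tiff", function(p) write_mask_tiff(ms_mask(traj$measurements), p))
    emit("recon_idw.tiff", function(p) write_image_tiff(traj$final_idw, p))
    emit("recon_biharmonic.tiff",
         function(p) write_image_tiff(traj$final_biharmonic, p))
    if (!is.null(maps)) {
      emit("comx.tiff", function(p) write_image_tiff(maps$inpainted$comx, p))
      emit("comy.tiff", function(p) write_image_tiff(maps$inpainted$comy, p))
      emit("com.csv", function(p) write_com_csv(maps, p))
    }
    TRUE
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    FALSE
  })
  manifest$complete <- ok
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"), manifest_path)
  if (!ok) stop("run output incomplete: ", manifest$error, call. = FALSE)
  invisible(manifest)
}
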