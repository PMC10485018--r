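# Post-analysis of diffraction stacks: ROI integration to dark-field values
# and per-point center-of-mass (CoMx/CoMy) shift maps, from full or sparse
# scans, with biharmonic inpainting of the sparse maps.

#' Detector region of interest
#'
#' Half-open pixel intervals `[row_min, row_max)` x `[col_min, col_max)` on
#' the detector, 1-based.
#'
#' @param row_min,row_max,col_min,col_max Integer bounds.
#' @param det_shape Optional (det_rows, det_cols) to validate against.
#' @return An object of class `detector_roi`.
#' @export
detector_roi <- function(row_min, row_max, col_min, col_max,
                         det_shape = NULL) {
  stop_if(row_min >= row_max || col_min >= col_max, "empty ROI")
  stop_if(row_min < 1 || col_min < 1, "ROI outside detector bounds")
  if (!is.null(det_shape)) {
    stop_if(row_max > det_shape[1L] + 1L || col_max > det_shape[2L] + 1L,
            "ROI outside detector bounds")
  }
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = "detector_roi")
}

#' @keywords internal
roi_rows <- function(roi) roi$row_min:(roi$row_max - 1L)
#' @keywords internal
roi_cols <- function(roi) roi$col_min:(roi$col_max - 1L)

#' Integrated intensity of a detector pattern over an ROI
#'
#' @param pattern Detector image matrix (non-negative).
#' @param roi A [detector_roi()].
#' @return Non-negative scalar sum over the ROI.
#' @export
roi_integrate <- function(pattern, roi) {
  stopifnot(inherits(roi, "detector_roi"))
  stop_if(roi$row_max - 1L > nrow(pattern) || roi$col_max - 1L > ncol(pattern),
          "ROI outside detector bounds")
  sum(pattern[roi_rows(roi), roi_cols(roi)])
}

#' Center-of-mass shift of a detector pattern
#'
#' Intensity-weighted mean detector coordinate within the ROI, reported as
#' the shift relative to the nominal peak center: `comx` is the column
#' (horizontal) shift and `comy` the row (vertical) shift, in detector
#' pixels, signed as measured minus nominal.
#'
#' @param pattern Detector image matrix.
#' @param roi A [detector_roi()].
#' @param nominal_center Length-2 (det_row, det_col) of the nominal peak.
#' @return List with `comx`, `comy`. Zero ROI intensity is an error
#'   (the shift is undefined, not zero).
#' @export
pattern_com <- function(pattern, roi, nominal_center) {
  rr <- roi_rows(roi); cc <- roi_cols(roi)
  sub <- pattern[rr, cc, drop = FALSE]
  tot <- sum(sub)
  stop_if(tot <= 0, "zero ROI intensity: center of mass undefined")
  wr <- rowSums(sub); wc <- colSums(sub)
  list(comx = sum(wc * cc) / tot - nominal_center[2L],
       comy = sum(wr * rr) / tot - nominal_center[1L])
}

#' Center-of-mass maps from a (possibly sparse) scan of a diffraction stack
#'
#' Computes the per-point CoMx/CoMy shift at every measured scan pixel, then
#' inpaints the two maps independently by biharmonic inpainting over the
#' valid measured pixels. Pixels with zero ROI intensity are flagged invalid
#' and excluded from the inpainting boundary data.
#'
#' @param stack A [generate_diffraction_stack()] result.
#' @param mask Logical scan-grid matrix of measured pixels (nonempty).
#' @param roi A [detector_roi()].
#' @return An object of class `com_maps`: list with `sparse` (list of `comx`,
#'   `comy`, `valid`: values only at valid measured pixels, `NA` elsewhere)
#'   and `inpainted` (full `comx`, `comy` matrices).
#' @export
com_maps_from_scan <- function(stack, mask, roi) {
  stopifnot(inherits(stack, "diffraction_stack"))
  stop_if(!any(mask), "empty measurement mask")
  rows <- dim(stack$patterns)[1L]; cols <- dim(stack$patterns)[2L]
  stop_if(nrow(mask) != rows || ncol(mask) != cols,
          "mask shape differs from the scan grid")
  comx <- matrix(NA_real_, rows, cols)
  comy <- matrix(NA_real_, rows, cols)
  valid <- matrix(FALSE, rows, cols)
  idx <- which(mask)
  for (i in idx) {
    rc <- index_to_coords(i, rows)
    pat <- stack$patterns[rc[1L], rc[2L], , ]
    if (roi_integrate(pat, roi) > 0) {
      cm <- pattern_com(pat, roi, stack$nominal_center)
      comx[i] <- cm$comx; comy[i] <- cm$comy
      valid[i] <- TRUE
    }
  }
  stop_if(!any(valid), "all measured pixels have zero ROI intensity")
  inpaint_field <- function(field) {
    vidx <- which(valid)
    coords <- index_to_coords(vidx, rows)
    m <- measurement_set(coords, field[vidx], c(rows, cols))
    biharmonic_inpaint(m)
  }
  structure(list(sparse = list(comx = comx, comy = comy, valid = valid),
                 inpainted = list(comx = inpaint_field(comx),
                                  comy = inpaint_field(comy)),
                 nominal_center = stack$nominal_center),
            class = "com_maps")
}

#' @export
print.com_maps <- function(x, ...) {
  cat(sprintf("<com_maps> %d valid measured pixels on a %d x %d grid\n",
              sum(x$sparse$valid), nrow(x$sparse$comx), ncol(x$sparse$comx)))
  cat(sprintf("  comx range [%.3f, %.3f], comy range [%.3f, %.3f] (detector px)\n",
              min(x$inpainted$comx), max(x$inpainted$comx),
              min(x$inpainted$comy), max(x$inpainted$comy)))
  invisible(x)
}

#' Optional hot-pixel filter for detector patterns
#'
#' Median-clip filter: pixels exceeding `factor` times the median of their
#' 3 x 3 neighborhood are replaced by that median. Off by default in the
#' analysis chain (synthetic data has no hot pixels).
#'
#' @param pattern Detector image matrix.
#' @param factor Clip threshold multiplier (default 10).
#' @return Filtered pattern matrix.
#' @export
filter_hot_pixels <- function(pattern, factor = 10) {
  rows <- nrow(pattern); cols <- ncol(pattern)
  p <- pattern[c(1L, seq_len(rows), rows), c(1L, seq_len(cols), cols)]
  med <- matrix(0, rows, cols)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      med[i, j] <- stats::median(p[i:(i + 2L), j:(j + 2L)])
    }
  }
  hot <- pattern > factor * pmax(med, .Machine$double.eps)
  out <- pattern
  out[hot] <- med[hot]
  out
}
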