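# Reconstruction quality metrics: distortion (squared L2), NRMSE, SSIM.

#' Distortion between ground truth and reconstruction
#'
#' The squared L2 norm of the pixelwise difference, summed over the image:
#' the quantity whose expected reduction drives measurement selection.
#'
#' @param a,b Numeric matrices of equal shape.
#' @return A non-negative scalar; 0 iff the images are equal.
#' @export
distortion <- function(a, b) {
  stop_if(!all(dim(a) == dim(b)), "image shapes differ")
  sum((a - b)^2)
}

#' Normalized root mean square error
#'
#' RMSE divided by the dynamic range (max - min) of the ground truth.
#' Lower is better.
#'
#' @param truth Ground-truth numeric matrix (non-constant).
#' @param est Estimate of the same shape.
#' @return A non-negative scalar.
#' @export
nrmse <- function(truth, est) {
  stop_if(!all(dim(truth) == dim(est)), "image shapes differ")
  rng <- max(truth) - min(truth)
  stop_if(rng == 0, "ground truth has zero dynamic range")
  sqrt(mean((truth - est)^2)) / rng
}

#' Structural similarity index
#'
#' Mean local SSIM with uniform square windows (default 7 x 7) and fixed data
#' range. Local means, variances and covariance are computed over the valid
#' (fully inside) window positions; variances use the unbiased n/(n-1)
#' normalization. Higher is better; 1 means identical images.
#'
#' @param truth,est Numeric matrices of equal shape.
#' @param win_size Odd window side length (default 7).
#' @param data_range Value range of the data (default 1 for normalized
#'   intensities).
#' @return A scalar in [-1, 1].
#' @export
ssim <- function(truth, est, win_size = 7L, data_range = 1) {
  stop_if(!all(dim(truth) == dim(est)), "image shapes differ")
  stop_if(win_size %% 2L != 1L, "win_size must be odd")
  stop_if(min(dim(truth)) < win_size,
          "image smaller than the SSIM window")
  np <- win_size^2
  mu_x <- valid_window_sums(truth, win_size) / np
  mu_y <- valid_window_sums(est, win_size) / np
  sxx <- valid_window_sums(truth^2, win_size) / np
  syy <- valid_window_sums(est^2, win_size) / np
  sxy <- valid_window_sums(truth * est, win_size) / np
  cov_norm <- np / (np - 1)
  vx <- cov_norm * (sxx - mu_x^2)
  vy <- cov_norm * (syy - mu_y^2)
  cxy <- cov_norm * (sxy - mu_x * mu_y)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mu_x * mu_y + c1) * (2 * cxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (vx + vy + c2))
  mean(s)
}
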