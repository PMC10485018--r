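# Simulated instrument: ground-truth dark-field samples (flakes with discrete
# thickness levels, dark bubble rims, zero background), per-pixel diffraction
# stacks with curvature-shifted peaks, and noisy point measurements.

#' Simulator configuration
#'
#' Describes a synthetic dark-field test object: a scan grid holding a number
#' of flakes, each drawn at one of a set of discrete thickness (brightness)
#' levels on a zero-intensity background, optionally decorated with circular
#' bubbles whose rims appear as locally depressed (dark) intensity.
#'
#' @param rows,cols Scan-grid dimensions in pixels (positive integers).
#' @param n_flakes Number of flakes to draw (>= 0).
#' @param thickness_levels Sorted ascending vector of intensity levels in
#'   (0, 1]; each flake takes one level.
#' @param n_bubbles_per_flake Number of bubbles per flake (>= 0).
#' @param bubble_radius_range Length-2 vector (min, max) bubble radius in
#'   pixels.
#' @param rim_contrast Relative depression of the bubble rim in (0, 1]: rim
#'   pixels take `level * (1 - rim_contrast)`.
#' @param background_level Intensity of flake-free pixels (default 0, matching
#'   dark-field images where bare substrate does not diffract into the ROI).
#' @param flake_area_fraction Target total fraction of the grid covered by
#'   flakes (default 0.3), split evenly across flakes.
#' @param seed Integer seed; the generated scene is a pure function of the
#'   configuration including this seed.
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(rows, cols, n_flakes = 3L,
                             thickness_levels = c(0.35, 0.65, 1.0),
                             n_bubbles_per_flake = 2L,
                             bubble_radius_range = c(4, 8),
                             rim_contrast = 0.8,
                             background_level = 0,
                             flake_area_fraction = 0.3,
                             seed = 1L) {
  stop_if(length(rows) != 1L || length(cols) != 1L || rows < 1 || cols < 1,
          "rows and cols must be positive integers")
  stop_if(n_flakes < 0, "n_flakes must be >= 0")
  stop_if(length(thickness_levels) == 0L, "thickness_levels must be nonempty")
  stop_if(is.unsorted(thickness_levels),
          "thickness_levels must be sorted ascending")
  stop_if(any(thickness_levels <= 0) || any(thickness_levels > 1),
          "thickness_levels must lie in (0, 1]")
  stop_if(length(bubble_radius_range) != 2L ||
            bubble_radius_range[1L] > bubble_radius_range[2L],
          "bubble_radius_range must be (min, max) with min <= max")
  stop_if(bubble_radius_range[2L] > min(rows, cols) / 2,
          "bubble radius may not exceed min(rows, cols)/2")
  stop_if(rim_contrast <= 0 || rim_contrast > 1,
          "rim_contrast must be in (0, 1]")
  stop_if(background_level < 0 || background_level > 1,
          "background_level must be in [0, 1]")
  stop_if(flake_area_fraction <= 0 || flake_area_fraction >= 1,
          "flake_area_fraction must be in (0, 1)")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 n_flakes = as.integer(n_flakes),
                 thickness_levels = as.numeric(thickness_levels),
                 n_bubbles_per_flake = as.integer(n_bubbles_per_flake),
                 bubble_radius_range = as.numeric(bubble_radius_range),
                 rim_contrast = as.numeric(rim_contrast),
                 background_level = as.numeric(background_level),
                 flake_area_fraction = as.numeric(flake_area_fraction),
                 seed = as.integer(seed)),
            class = "simulator_config")
}

#' Measurement noise model
#'
#' @param kind One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param parameter Noise scale: standard deviation for `gaussian`, expected
#'   counts at unit intensity for `poisson`. Ignored for `none`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian", "poisson"),
                        parameter = 0) {
  kind <- match.arg(kind)
  stop_if(parameter < 0, "noise parameter must be >= 0")
  structure(list(kind = kind, parameter = as.numeric(parameter)),
            class = "noise_model")
}

# Evaluate code with a temporary RNG state seeded by `seed`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Build the full synthetic scene: intensity image plus flake/bubble geometry.
# Used by both the image generator and the diffraction-stack generator so the
# two stay consistent for a given config.
#' @keywords internal
simulate_scene <- function(config) {
  stopifnot(inherits(config, "simulator_config"))
  rows <- config$rows; cols <- config$cols
  img <- matrix(config$background_level, rows, cols)
  flakes <- list(); bubbles <- list()
  if (config$n_flakes > 0L) {
    with_seed(substream_seed(config$seed, 1L), {
      per_flake_area <- config$flake_area_fraction * rows * cols /
        config$n_flakes
      for (f in seq_len(config$n_flakes)) {
        r0 <- sqrt(per_flake_area / pi)
        u <- stats::runif(1, 0.85, 1.18)
        a <- r0 * u; b <- r0 / u
        theta <- stats::runif(1, 0, pi)
        cr <- stats::runif(1, 1 + 0.25 * rows, rows - 0.25 * rows)
        cc <- stats::runif(1, 1 + 0.25 * cols, cols - 0.25 * cols)
        lev <- sample(config$thickness_levels, 1L)
        dr <- matrix(seq_len(rows) - cr, rows, cols)
        dc <- matrix(seq_len(cols) - cc, rows, cols, byrow = TRUE)
        uu <- dr * cos(theta) + dc * sin(theta)
        vv <- -dr * sin(theta) + dc * cos(theta)
        inside <- (uu / a)^2 + (vv / b)^2 <= 1
        img[inside] <- lev
        flakes[[f]] <- list(center = c(cr, cc), axes = c(a, b),
                            angle = theta, level = lev)
        if (config$n_bubbles_per_flake > 0L && any(inside)) {
          in_idx <- which(inside)
          for (bidx in seq_len(config$n_bubbles_per_flake)) {
            ctr_i <- in_idx[sample.int(length(in_idx), 1L)]
            bc <- index_to_coords(ctr_i, rows)
            br <- stats::runif(1, config$bubble_radius_range[1L],
                               config$bubble_radius_range[2L])
            bubbles[[length(bubbles) + 1L]] <-
              list(center = as.numeric(bc), radius = br, flake = f)
          }
        }
      }
    })
  }
  # Bubble rims: annulus depressed relative to the surrounding flake.
  for (bub in bubbles) {
    d <- pixel_distances(rows, cols, bub$center)
    rim_w <- max(1.5, 0.3 * bub$radius)
    rim <- d <= bub$radius & d >= bub$radius - rim_w & img > config$background_level
    img[rim] <- img[rim] * (1 - config$rim_contrast)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, flakes = flakes, bubbles = bubbles, config = config)
}

#' @keywords internal
pixel_distances <- function(rows, cols, center) {
  dr <- matrix(seq_len(rows) - center[1L], rows, cols)
  dc <- matrix(seq_len(cols) - center[2L], rows, cols, byrow = TRUE)
  sqrt(dr^2 + dc^2)
}

#' Generate a synthetic flake-and-bubble dark-field image
#'
#' Draws `n_flakes` elliptical flakes at discrete thickness levels on a
#' constant background, then depresses annular bubble rims (`rim_contrast`)
#' to emulate the dark rings that film curvature produces in a dark-field
#' scan. Deterministic for a fixed configuration.
#'
#' @param config A [simulator_config()].
#' @return A `rows x cols` numeric matrix in [0, 1] with attributes `flakes`,
#'   `bubbles` (scene geometry) and `config`.
#' @export
generate_flake_image <- function(config) {
  scene <- simulate_scene(config)
  img <- scene$image
  attr(img, "flakes") <- scene$flakes
  attr(img, "bubbles") <- scene$bubbles
  attr(img, "config") <- config
  img
}

# Height field of the bubbles (spherical caps) and its spatial gradient.
# Returns list(h, gx, gy): gx = d h / d col, gy = d h / d row.
#' @keywords internal
bubble_height_field <- function(scene) {
  rows <- scene$config$rows; cols <- scene$config$cols
  h <- matrix(0, rows, cols); gx <- matrix(0, rows, cols)
  gy <- matrix(0, rows, cols)
  for (bub in scene$bubbles) {
    R <- bub$radius; h0 <- 0.4 * R
    Rc <- (R^2 + h0^2) / (2 * h0)
    dr <- matrix(seq_len(rows) - bub$center[1L], rows, cols)
    dc <- matrix(seq_len(cols) - bub$center[2L], rows, cols, byrow = TRUE)
    d <- sqrt(dr^2 + dc^2)
    inside <- d < R
    hz <- sqrt(pmax(Rc^2 - d^2, 0)) - (Rc - h0)
    dh <- -d / sqrt(pmax(Rc^2 - d^2, 1e-12))   # d h / d (radial distance)
    ux <- ifelse(d > 0, dc / d, 0)
    uy <- ifelse(d > 0, dr / d, 0)
    h[inside] <- h[inside] + hz[inside]
    gx[inside] <- gx[inside] + (dh * ux)[inside]
    gy[inside] <- gy[inside] + (dh * uy)[inside]
  }
  list(h = h, gx = gx, gy = gy)
}

#' Generate a per-pixel diffraction stack for a simulated scene
#'
#' Each scan pixel gets a 2D Gaussian detector pattern whose total intensity
#' equals the pixel's dark-field value and whose center is displaced from the
#' nominal position by `shift_gain` times the local gradient of the simulated
#' film-height field (bubbles modelled as spherical caps). Flat regions give
#' a peak at the nominal center; zero-intensity background pixels give an
#' all-zero pattern.
#'
#' @param sample_config A [simulator_config()]; the same config (and seed)
#'   reproduces the scene of [generate_flake_image()].
#' @param det_rows,det_cols Detector dimensions in pixels (>= 8).
#' @param peak_sigma Gaussian peak width in detector pixels (> 0).
#' @param shift_gain Detector-pixel shift per unit height gradient.
#' @return An object of class `diffraction_stack`: list with `patterns`
#'   (4-D array rows x cols x det_rows x det_cols), `nominal_center`
#'   (det_row, det_col) and `config`.
#' @export
generate_diffraction_stack <- function(sample_config, det_rows = 24L,
                                       det_cols = 24L, peak_sigma = 1.5,
                                       shift_gain = 4) {
  stop_if(det_rows < 8 || det_cols < 8, "detector dims must be >= 8")
  stop_if(peak_sigma <= 0, "peak_sigma must be > 0")
  scene <- simulate_scene(sample_config)
  hf <- bubble_height_field(scene)
  rows <- sample_config$rows; cols <- sample_config$cols
  nominal <- c((det_rows + 1) / 2, (det_cols + 1) / 2)
  ctr_r <- nominal[1L] + shift_gain * hf$gy
  ctr_c <- nominal[2L] + shift_gain * hf$gx
  # keep peaks on-detector: clip centers that the shift pushed outside
  margin <- 1
  clipped <- ctr_r < margin | ctr_r > det_rows - margin + 1 |
    ctr_c < margin | ctr_c > det_cols - margin + 1
  if (any(clipped & scene$image > 0)) {
    warning("peak shift exceeded detector bounds at ",
            sum(clipped & scene$image > 0), " pixel(s); centers clipped")
  }
  ctr_r <- pmin(pmax(ctr_r, margin), det_rows - margin + 1)
  ctr_c <- pmin(pmax(ctr_c, margin), det_cols - margin + 1)
  det_r <- seq_len(det_rows); det_c <- seq_len(det_cols)
  patterns <- array(0, dim = c(rows, cols, det_rows, det_cols))
  s2 <- 2 * peak_sigma^2
  for (j in seq_len(cols)) {
    for (i in seq_len(rows)) {
      v <- scene$image[i, j]
      if (v <= 0) next
      pr <- exp(-(det_r - ctr_r[i, j])^2 / s2)
      pc <- exp(-(det_c - ctr_c[i, j])^2 / s2)
      pat <- outer(pr, pc)
      patterns[i, j, , ] <- pat * (v / sum(pat))
    }
  }
  structure(list(patterns = patterns, nominal_center = nominal,
                 config = sample_config,
                 det_shape = c(as.integer(det_rows), as.integer(det_cols))),
            class = "diffraction_stack")
}

#' Simulate a single point measurement
#'
#' Returns the sample value at a scan position under the given noise model.
#' Results are clipped at zero (intensities cannot go negative).
#'
#' @param sample Numeric matrix (the ground-truth image).
#' @param point Length-2 integer vector (row, col), 1-based, inside the grid.
#' @param noise A [noise_model()] (default: exact).
#' @return A single non-negative numeric value.
#' @export
measure_point <- function(sample, point, noise = noise_model("none")) {
  stopifnot(inherits(noise, "noise_model"))
  r <- point[1L]; cl <- point[2L]
  stop_if(r < 1 || r > nrow(sample) || cl < 1 || cl > ncol(sample),
          "measurement point (%d, %d) outside the scan grid", r, cl)
  v <- sample[r, cl]
  out <- switch(noise$kind,
    none = v,
    gaussian = v + stats::rnorm(1L, 0, noise$parameter),
    poisson = if (noise$parameter == 0) v else
      stats::rpois(1L, noise$parameter * v) / noise$parameter)
  max(out, 0)
}

# Vectorized measurement of many points (used by the scan loop).
#' @keywords internal
measure_points <- function(sample, coords, noise = noise_model("none")) {
  n <- nrow(coords)
  bad <- coords[, 1L] < 1 | coords[, 1L] > nrow(sample) |
    coords[, 2L] < 1 | coords[, 2L] > ncol(sample)
  stop_if(any(bad), "measurement point outside the scan grid")
  v <- sample[coords_to_index(coords, nrow(sample))]
  out <- switch(noise$kind,
    none = v,
    gaussian = v + stats::rnorm(n, 0, noise$parameter),
    poisson = if (noise$parameter == 0) v else
      stats::rpois(n, noise$parameter * v) / noise$parameter)
  pmax(out, 0)
}

#' Load the bundled photographic training image
#'
#' Reads the package's 128 x 128 grayscale copy of the standard public-domain
#' "cameraman" photographic test image (ASCII PGM), normalized to [0, 1].
#' This image has no relation to microscopy: training the decision model on
#' it is what makes the model sample-agnostic.
#'
#' @param path Path to an ASCII (P2) PGM file; defaults to the bundled image.
#' @return Numeric matrix in [0, 1].
#' @export
load_training_image <- function(path = system.file("extdata",
                                                   "cameraman_128.pgm",
                                                   package = "sladscan")) {
  stop_if(!file.exists(path), "PGM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  tok <- scan(text = paste(lines, collapse = "\n"), what = character(),
              quiet = TRUE)
  stop_if(tok[1L] != "P2", "not an ASCII (P2) PGM file")
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  maxval <- as.numeric(tok[4L])
  vals <- as.numeric(tok[-(1:4)])
  stop_if(length(vals) != w * h, "corrupt PGM: wrong pixel count")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Generic training image
#'
#' A deterministic, procedurally generated grayscale scene (smooth
#' illumination gradient, geometric shapes at several gray levels, mild
#' sinusoidal texture, light smoothing) used to train the default decision
#' model. It is synthetic and deliberately unrelated to the flake-and-bubble
#' simulator: training on it exercises the sample-agnostic property of the
#' decision engine.
#'
#' @param size Side length in pixels (default 128).
#' @return A `size x size` numeric matrix in [0, 1].
#' @export
generic_training_image <- function(size = 128L) {
  stop_if(size < 16, "size must be >= 16")
  n <- as.integer(size)
  rr <- matrix(seq_len(n) / n, n, n)
  cc <- matrix(seq_len(n) / n, n, n, byrow = TRUE)
  img <- 0.25 + 0.35 * cc + 0.1 * rr            # illumination ramp
  img <- img + 0.05 * sin(2 * pi * 3.1 * rr) * sin(2 * pi * 2.3 * cc)
  with_seed(1234L, {
    for (k in seq_len(14L)) {
      lev <- stats::runif(1, 0, 1)
      ctr <- stats::runif(2, 0.1, 0.9) * n
      if (k %% 2L == 0L) {            # disc
        rad <- stats::runif(1, 0.05, 0.22) * n
        d <- pixel_distances(n, n, ctr)
        img[d <= rad] <- lev
      } else {                        # rotated rectangle
        hw <- stats::runif(2, 0.04, 0.2) * n
        th <- stats::runif(1, 0, pi)
        dr <- matrix(seq_len(n) - ctr[1L], n, n)
        dc <- matrix(seq_len(n) - ctr[2L], n, n, byrow = TRUE)
        u <- dr * cos(th) + dc * sin(th)
        v <- -dr * sin(th) + dc * cos(th)
        img[abs(u) <= hw[1L] & abs(v) <= hw[2L]] <- lev
      }
    }
  })
  img <- box_blur(img)
  img <- img - min(img)
  img / max(img)
}

# 3x3 box blur with replicated edges.
#' @keywords internal
box_blur <- function(x) {
  rows <- nrow(x); cols <- ncol(x)
  p <- x[c(1L, seq_len(rows), rows), c(1L, seq_len(cols), cols)]
  out <- matrix(0, rows, cols)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out + p[dr + seq_len(rows), dc + seq_len(cols)]
  }
  out / 9
}
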