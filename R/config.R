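# Run configuration: flat YAML-style key-value files mirroring the simulator,
# feature, scan and ROI parameters, with validated loading and round-trip
# writing.

#' @keywords internal
config_defaults <- function() {
  list(
    # simulator
    rows = 150L, cols = 100L, n_flakes = 3L,
    thickness_levels = c(0.35, 0.65, 1.0),
    n_bubbles_per_flake = 2L, bubble_radius_range = c(4, 8),
    rim_contrast = 0.8, background_level = 0,
    flake_area_fraction = 0.3, sim_seed = 1L,
    # features / decision model
    k = 10L, radius = NULL, rbf_dim = 50L, rbf_gamma = 1 / 24, rbf_seed = 7L,
    # acquisition loop
    initial_fraction = 0.01, batch_size = 50L, max_coverage = 0.35,
    stopping = "coverage_only", window = 5L, rel_tolerance = 0.02,
    checkpoint_coverages = numeric(0), scan_seed = 1L,
    # noise
    noise_kind = "none", noise_parameter = 0,
    # detector ROI (defaults cover the default 24 x 24 detector)
    roi_row_min = 1L, roi_row_max = 25L, roi_col_min = 1L, roi_col_max = 25L)
}

#' Load and validate a run configuration
#'
#' Reads a flat YAML key-value file whose keys mirror the simulator, feature,
#' scan and ROI parameters. Unknown keys are rejected by name; missing keys
#' take the documented defaults (an empty file yields the full default
#' configuration: 1% initialization, batches of 50, k = 10, ...). Values are
#' validated by the respective constructors, which report the offending field.
#'
#' @param path Path to the config file.
#' @return A list with validated elements `simulator`
#'   ([simulator_config()]), `features` ([feature_config()]), `scan`
#'   ([scan_config()]), `noise` ([noise_model()]), `roi` ([detector_roi()])
#'   and `raw` (the merged flat key-value list).
#' @export
load_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  stop_if(length(unknown) > 0L,
          "unknown config key(s): %s", paste(unknown, collapse = ", "))
  raw <- utils::modifyList(defaults, user, keep.null = TRUE)
  validate_config(raw)
}

#' @keywords internal
validate_config <- function(raw) {
  # YAML sequences load as lists: flatten the vector-valued keys
  for (key in c("thickness_levels", "bubble_radius_range",
                "checkpoint_coverages")) {
    raw[[key]] <- as.numeric(unlist(raw[[key]]))
  }
  sim <- simulator_config(rows = raw$rows, cols = raw$cols,
                          n_flakes = raw$n_flakes,
                          thickness_levels = raw$thickness_levels,
                          n_bubbles_per_flake = raw$n_bubbles_per_flake,
                          bubble_radius_range = raw$bubble_radius_range,
                          rim_contrast = raw$rim_contrast,
                          background_level = raw$background_level,
                          flake_area_fraction = raw$flake_area_fraction,
                          seed = raw$sim_seed)
  feats <- feature_config(k = raw$k, radius = raw$radius,
                          rbf_dim = raw$rbf_dim, rbf_gamma = raw$rbf_gamma,
                          rbf_seed = raw$rbf_seed)
  scan <- scan_config(initial_fraction = raw$initial_fraction,
                      batch_size = raw$batch_size,
                      max_coverage = raw$max_coverage,
                      stopping = stopping_rule(raw$stopping,
                                               window = raw$window,
                                               rel_tolerance = raw$rel_tolerance),
                      checkpoint_coverages = raw$checkpoint_coverages,
                      seed = raw$scan_seed)
  noise <- noise_model(raw$noise_kind, raw$noise_parameter)
  roi <- detector_roi(raw$roi_row_min, raw$roi_row_max,
                      raw$roi_col_min, raw$roi_col_max)
  list(simulator = sim, features = feats, scan = scan, noise = noise,
       roi = roi, raw = raw)
}

#' Write a configuration back to a YAML file
#'
#' Writes the flat key-value form of a configuration (as returned in the
#' `raw` element of [load_config()]); `load_config(write_config(cfg, path))`
#' reproduces the configuration.
#'
#' @param config A [load_config()] result or a flat key-value list.
#' @param path Destination path.
#' @export
write_config <- function(config, path) {
  raw <- if (!is.null(config$raw)) config$raw else config
  raw <- raw[!vapply(raw, is.null, logical(1L))]
  raw <- raw[vapply(raw, length, integer(1L)) > 0L]
  yaml::write_yaml(raw, path, precision = 15L)
  invisible(path)
}
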