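#' Run configuration
#'
#' Builds the resolved configuration object used across the pipeline. All
#' physical sizes are in micrometres and hours unless noted. Defaults mirror
#' the acquisition protocol the pipeline was designed around: confocal
#' half-stacks in 3 um z-steps imaged every 2 h for 12 h for spheroids, and
#' 10 s frames over 15 min movies for cell-couple imaging.
#'
#' @param voxel_size numeric length-3, physical voxel size `c(dx, dy, dz)` in
#'   micrometres. `dz` defaults to the 3 um acquisition z-step.
#' @param frame_interval_s frame spacing of cell-couple movies, seconds.
#' @param imaging_interval_h spacing of spheroid timepoints, hours.
#' @param movie_duration_min duration of cell-couple movies, minutes.
#' @param cytotox_step_min sampling interval of cytotoxicity series, minutes.
#' @param threshold_method binarisation method for the spheroid channel,
#'   `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity cutoff used when `threshold_method`
#'   is `"fixed"`.
#' @param alpha alpha-hull fill radius in micrometres, or `"auto"` for the
#'   critical-alpha search (smallest radius on a doubling grid at which the
#'   foreground component count stabilises).
#' @param min_volume_um3 minimum spheroid component volume retained.
#' @param min_cell_volume_um3 minimum T-cell detection volume; default is the
#'   volume of an 8 um diameter sphere.
#' @param expected_radius_um typical spheroid radius; sets the minimum
#'   separation of watershed seed maxima.
#' @param spread_fraction fraction of the track-maximum interface length that
#'   counts as a "maximally spread" synapse.
#' @param lamella_sector_deg minimum angle (degrees) between a protrusion and
#'   the synapse direction for an off-interface lamella.
#' @param lamella_area_frac minimum protrusion area as a fraction of cell area.
#' @param cytotox_window_points OLS window length (samples) for the steepest
#'   killing slope; default 8 samples = 2 h at 15-min spacing.
#' @param cytotox_normalization `"difference"` (control slope minus target
#'   slope) or `"ratio"`.
#' @param rng_seed integer seed recorded and used by generators when their
#'   `seed` argument is missing.
#' @return an object of class `spherotil_config` (a validated named list).
#' @export
spherotil_config <- function(voxel_size = c(3, 3, 3),
                             frame_interval_s = 10,
                             imaging_interval_h = 2,
                             movie_duration_min = 15,
                             cytotox_step_min = 15,
                             threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NA_real_,
                             alpha = "auto",
                             min_volume_um3 = 1e4,
                             min_cell_volume_um3 = 4 / 3 * pi * 4^3,
                             expected_radius_um = 40,
                             spread_fraction = 0.95,
                             lamella_sector_deg = 90,
                             lamella_area_frac = 0.10,
                             cytotox_window_points = 8,
                             cytotox_normalization = c("difference", "ratio"),
                             rng_seed = 1L) {
  threshold_method <- match.arg(threshold_method)
  cytotox_normalization <- match.arg(cytotox_normalization)
  cfg <- list(
    voxel_size = as.numeric(voxel_size),
    frame_interval_s = frame_interval_s,
    imaging_interval_h = imaging_interval_h,
    movie_duration_min = movie_duration_min,
    cytotox_step_min = cytotox_step_min,
    threshold_method = threshold_method,
    fixed_threshold = fixed_threshold,
    alpha = alpha,
    min_volume_um3 = min_volume_um3,
    min_cell_volume_um3 = min_cell_volume_um3,
    expected_radius_um = expected_radius_um,
    spread_fraction = spread_fraction,
    lamella_sector_deg = lamella_sector_deg,
    lamella_area_frac = lamella_area_frac,
    cytotox_window_points = cytotox_window_points,
    cytotox_normalization = cytotox_normalization,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    length(cfg$voxel_size) == 3, all(cfg$voxel_size > 0),
    cfg$frame_interval_s > 0, cfg$imaging_interval_h > 0,
    cfg$movie_duration_min > 0, cfg$cytotox_step_min > 0,
    cfg$min_volume_um3 >= 0, cfg$min_cell_volume_um3 >= 0,
    cfg$expected_radius_um > 0,
    cfg$spread_fraction > 0, cfg$spread_fraction <= 1,
    cfg$lamella_sector_deg >= 0, cfg$lamella_sector_deg <= 180,
    cfg$lamella_area_frac > 0,
    cfg$cytotox_window_points >= 3
  )
  if (!identical(cfg$alpha, "auto")) stopifnot(is.numeric(cfg$alpha), cfg$alpha > 0)
  structure(cfg, class = "spherotil_config")
}

#' Read / write a configuration as JSON
#'
#' @param path file path of a JSON configuration.
#' @return `read_config` returns a validated `spherotil_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- Filter(Negate(is.null), raw)  # JSON nulls fall back to defaults
  do.call(spherotil_config,
          raw[names(raw) %in% names(formals(spherotil_config))])
}

#' @rdname read_config
#' @param config a `spherotil_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "spherotil_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.spherotil_config <- function(x, ...) {
  cat("<spherotil_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# Log the seed and the fully resolved configuration; every CLI entry point
# calls this once before doing work.
log_run <- function(config, seed, what = "run") {
  message(sprintf("[spherotil] %s | seed = %d", what, as.integer(seed)))
  message(sprintf("[spherotil] config: %s",
                  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)))
  invisible(NULL)
}
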