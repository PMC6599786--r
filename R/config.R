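#' Analysis configuration
#'
#' Collects every threshold used by the pipeline, with the values of the fin
#' whale singing/swimming study as defaults. Nothing downstream hard-codes a
#' threshold: song assembly, bout segmentation, duty-cycle windows, regime
#' classification and track inclusion all read from this object.
#'
#' @param min_notes minimum number of regularly spaced 20 Hz notes for a note
#'   run to count as a song (default 3).
#' @param ini_min,ini_max bounds (seconds) of the typical inter-note-interval
#'   band, reported per song as a regularity diagnostic (default 9-20 s).
#' @param note_break inter-note-interval (seconds) above which a note run is
#'   broken: intervals greater than this end the song (default 30 s).
#' @param duty_window trailing window length (minutes) over which the singing
#'   duty-cycle of a track segment is computed (default 30 min).
#' @param robust_threshold duty-cycle (percent) at or above which a segment is
#'   classified as robust singing (default 70).
#' @param speed_split swimming speed (km/h) at or above which a segment is in
#'   the fast regime (default 7, the cohort mean track speed rounded).
#' @param default_bec fallback bout-ending criterion (minutes) used when the
#'   biexponential fit cannot be estimated from the data at hand (default 35).
#' @param min_locations,min_track_duration track inclusion filter: at least
#'   this many locations and at least this duration in hours (defaults 3, 1 h).
#' @param bin_width histogram bin width (minutes) for the inter-song-interval
#'   log-frequency distribution (default 1).
#' @param speed_bin,duty_bin bin widths for the speed x duty-cycle histogram
#'   (defaults 1 km/h and 5 percentage points).
#' @param planar if `TRUE`, locations are planar x/y kilometre coordinates
#'   (synthetic scenarios); otherwise WGS84 lat/lon degrees.
#' @param rng_seed optional integer seed recorded with the configuration.
#'
#' @return an object of class `analysis_config` (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$speed_split
#' @export
analysis_config <- function(min_notes = 3L,
                            ini_min = 9,
                            ini_max = 20,
                            note_break = 30,
                            duty_window = 30,
                            robust_threshold = 70,
                            speed_split = 7,
                            default_bec = 35,
                            min_locations = 3L,
                            min_track_duration = 1,
                            bin_width = 1,
                            speed_bin = 1,
                            duty_bin = 5,
                            planar = FALSE,
                            rng_seed = NULL) {
  cfg <- list(min_notes = as.integer(min_notes), ini_min = ini_min,
              ini_max = ini_max, note_break = note_break,
              duty_window = duty_window, robust_threshold = robust_threshold,
              speed_split = speed_split, default_bec = default_bec,
              min_locations = as.integer(min_locations),
              min_track_duration = min_track_duration,
              bin_width = bin_width, speed_bin = speed_bin, duty_bin = duty_bin,
              planar = isTRUE(planar), rng_seed = rng_seed)
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  num <- c("min_notes", "ini_min", "ini_max", "note_break", "duty_window",
           "robust_threshold", "speed_split", "default_bec", "min_locations",
           "min_track_duration", "bin_width", "speed_bin", "duty_bin")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("config field '", f, "' must be a single positive number", call. = FALSE)
  }
  if (!(cfg$ini_min < cfg$ini_max && cfg$ini_max < cfg$note_break))
    stop("config requires ini_min < ini_max < note_break (got ",
         cfg$ini_min, ", ", cfg$ini_max, ", ", cfg$note_break, ")", call. = FALSE)
  if (cfg$robust_threshold > 100)
    stop("robust_threshold is a percentage and must be <= 100", call. = FALSE)
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  cat(sprintf("  song: >= %d notes, note break > %g s (typical INI %g-%g s)\n",
              x$min_notes, x$note_break, x$ini_min, x$ini_max))
  cat(sprintf("  duty-cycle: trailing %g min window, robust >= %g%%\n",
              x$duty_window, x$robust_threshold))
  cat(sprintf("  regimes: fast >= %g km/h; default BEC %g min\n",
              x$speed_split, x$default_bec))
  cat(sprintf("  track filter: >= %d locations, >= %g h; coordinates: %s\n",
              x$min_locations, x$min_track_duration,
              if (x$planar) "planar km" else "WGS84 lat/lon"))
  invisible(x)
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are ignored; recognized keys override [analysis_config()]
#' defaults.
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(analysis_config)))
  do.call(analysis_config, raw[keep])
}
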