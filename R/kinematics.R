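# Track kinematics: segments, speeds, trailing duty-cycles, regime
# classification, track-level summaries and inclusion filtering.

locations_planar <- function(locations) all(c("x_km", "y_km") %in% names(locations))

location_distance_km <- function(locations, i, j) {
  if (locations_planar(locations)) {
    sqrt((locations$x_km[j] - locations$x_km[i])^2 +
         (locations$y_km[j] - locations$y_km[i])^2)
  } else {
    great_circle_km(locations$lat[i], locations$lon[i],
                    locations$lat[j], locations$lon[j])
  }
}

#' Build track segments from successive localizations
#'
#' One segment per successive pair of locations of a singer: the distance
#' travelled (great-circle on a 6371 km sphere for lat/lon input, Euclidean
#' for planar km input), the elapsed time, and their ratio, the segment
#' swimming speed.
#'
#' @param locations localization table (see [read_locations()]); times must be
#'   strictly increasing within each singer.
#' @param cfg an [analysis_config()].
#' @return data frame with one row per segment: `singer_id`, `t_start`,
#'   `t_end` (epoch seconds), `distance_km`, `elapsed_h`, `speed_kmh`.
#' @export
build_segments <- function(locations, cfg = analysis_config()) {
  empty <- data.frame(singer_id = character(), t_start = numeric(),
                      t_end = numeric(), distance_km = numeric(),
                      elapsed_h = numeric(), speed_kmh = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(locations) || nrow(locations) < 2) return(empty)
  pieces <- lapply(split(seq_len(nrow(locations)), locations$singer_id), function(ix) {
    n <- length(ix)
    if (n < 2) return(NULL)
    ord <- ix[order(locations$time[ix])]
    i <- ord[-n]; j <- ord[-1]
    elapsed <- (locations$time[j] - locations$time[i]) / 3600
    if (any(elapsed <= 0))
      stop("zero or negative elapsed time between locations for singer '",
           locations$singer_id[ix[1]], "'", call. = FALSE)
    dist <- location_distance_km(locations, i, j)
    data.frame(singer_id = locations$singer_id[ix[1]],
               t_start = locations$time[i], t_end = locations$time[j],
               distance_km = dist, elapsed_h = elapsed,
               speed_kmh = dist / elapsed, stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Trailing-window singing duty-cycle of track segments
#'
#' For each segment, the duty-cycle is the percentage of time the singer was
#' singing during the last `cfg$duty_window` minutes of the segment. The
#' window is the trailing `duty_window` of the segment intersected with the
#' segment span: segments shorter than the window use their full span, and the
#' window length actually used is reported (`window_used_min`). Songs that
#' straddle a window edge contribute only their overlap (exact interval
#' intersection, no rasterization). Silence is silence regardless of bout
#' bookkeeping: between-bout gaps that fall inside a window count as
#' non-singing time.
#'
#' @param segments segment table from [build_segments()].
#' @param songs song table from [assemble_songs()].
#' @param cfg an [analysis_config()].
#' @return data frame with `duty_cycle_pct` (0-100) and `window_used_min`,
#'   one row per segment.
#' @export
segment_duty_cycle <- function(segments, songs, cfg = analysis_config()) {
  n <- nrow(segments)
  dc <- numeric(n); wu <- numeric(n)
  songs_by <- if (is.null(songs) || nrow(songs) == 0) list()
              else split(seq_len(nrow(songs)), songs$singer_id)
  s_start <- songs$start; s_end <- songs$end
  t_end <- segments$t_end; t_start <- segments$t_start
  sid <- segments$singer_id
  win_s <- cfg$duty_window * 60
  for (i in seq_len(n)) {
    we <- t_end[i]
    ws <- max(we - win_s, t_start[i])
    len <- we - ws
    if (len <= 0)
      stop("zero-length duty-cycle window for segment ", i, call. = FALSE)
    ix <- songs_by[[sid[i]]]
    ov <- if (is.null(ix)) 0 else
      sum(pmax(0, pmin(s_end[ix], we) - pmax(s_start[ix], ws)))
    dc[i] <- 100 * ov / len
    wu[i] <- len / 60
  }
  data.frame(duty_cycle_pct = dc, window_used_min = wu)
}

#' Classify duty-cycles as robust or intermittent singing
#'
#' Robust singing is a duty-cycle greater than or equal to the configured
#' threshold (70% by default); anything below is intermittent.
#' @param d duty-cycle(s) in percent.
#' @param cfg an [analysis_config()].
#' @return character vector, `"robust"` or `"intermittent"`.
#' @export
classify_duty_cycle <- function(d, cfg = analysis_config()) {
  ifelse(d >= cfg$robust_threshold, "robust", "intermittent")
}

#' Classify swimming speeds into slow/fast regimes
#'
#' Fast is a speed greater than or equal to the configured split (7 km/h by
#' default, the cohort mean track speed rounded to the nearest integer).
#' @param v speed(s) in km/h.
#' @param cfg an [analysis_config()].
#' @return character vector, `"slow"` or `"fast"`.
#' @export
classify_speed_regime <- function(v, cfg = analysis_config()) {
  ifelse(v >= cfg$speed_split, "fast", "slow")
}

#' Regime transition pattern of a track
#'
#' Summarizes the sequence of segment speed regimes: no regime change gives
#' `stayed_slow`/`stayed_fast`, exactly one change gives `switched_to_fast` or
#' `switched_to_slow` (named for the final regime), and two or more changes
#' give `alternating`. Fewer than two segments is `undefined` (with a
#' warning): a single speed cannot exhibit a pattern.
#'
#' @param regimes character vector of `"slow"`/`"fast"` segment regimes, or a
#'   `singer_track` whose segments carry a `regime` column.
#' @return one of `"stayed_slow"`, `"stayed_fast"`, `"switched_to_fast"`,
#'   `"switched_to_slow"`, `"alternating"`, `"undefined"`.
#' @export
transition_pattern <- function(regimes) {
  if (inherits(regimes, "singer_track")) regimes <- regimes$segments$regime
  n <- length(regimes)
  if (n < 2) {
    warning("transition pattern undefined for fewer than 2 segments")
    return("undefined")
  }
  changes <- sum(regimes[-1] != regimes[-n])
  if (changes == 0) return(paste0("stayed_", regimes[1]))
  if (changes == 1) return(paste0("switched_to_", regimes[n]))
  "alternating"
}

#' Assemble a singer track
#'
#' Bundles one singer's locations, segments (with duty-cycle and regime
#' columns added), songs and bouts, together with the track-level summaries:
#' track-length (sum of segment distances), track-duration (first to last
#' location) and total-singing-duration (start of the first song in the first
#' bout to the end of the last song in the last bout; equal to the bout
#' duration for a single-bout singer).
#'
#' @param singer_id singer identifier.
#' @param locations this singer's localization rows.
#' @param segments this singer's segments (regime/duty columns added here if
#'   missing).
#' @param songs this singer's songs.
#' @param bouts this singer's bout table from [segment_bouts()].
#' @param cfg an [analysis_config()].
#' @return an object of class `singer_track`.
#' @export
singer_track <- function(singer_id, locations, segments, songs, bouts,
                         cfg = analysis_config()) {
  if (!is.null(segments) && nrow(segments) > 0) {
    if (is.null(segments$duty_cycle_pct)) {
      dd <- segment_duty_cycle(segments, songs, cfg)
      segments$duty_cycle_pct <- dd$duty_cycle_pct
      segments$window_used_min <- dd$window_used_min
    }
    segments$regime <- classify_speed_regime(segments$speed_kmh, cfg)
    segments$dc_class <- classify_duty_cycle(segments$duty_cycle_pct, cfg)
  }
  structure(list(singer_id = singer_id, locations = locations,
                 segments = segments, songs = songs, bouts = bouts,
                 track_length_km = sum(segments$distance_km %||% 0),
                 track_duration_h =
                   (max(locations$time) - min(locations$time)) / 3600,
                 total_singing_duration_h =
                   if (!is.null(songs) && nrow(songs) > 0)
                     (max(songs$end) - min(songs$start)) / 3600
                   else NA_real_),
            class = "singer_track")
}

#' @export
print.singer_track <- function(x, ...) {
  cat(sprintf("Singer track '%s': %d locations, %d segments, %d songs, %d bout(s)\n",
              x$singer_id, nrow(x$locations), nrow(x$segments),
              if (is.null(x$songs)) 0L else nrow(x$songs),
              if (is.null(x$bouts)) 0L else nrow(x$bouts)))
  cat(sprintf("  track length %.1f km, duration %.2f h, total singing %.2f h\n",
              x$track_length_km, x$track_duration_h, x$total_singing_duration_h))
  invisible(x)
}

#' Track-level summary of a singer track
#'
#' Recomputes the track-level quantities from the constituent parts.
#' @param track a `singer_track`.
#' @return named numeric vector: `track_length_km`, `track_duration_h`,
#'   `total_singing_duration_h`, `n_locations`, `n_segments`, `n_songs`,
#'   `n_bouts`.
#' @export
track_summaries <- function(track) {
  c(track_length_km = sum(track$segments$distance_km %||% 0),
    track_duration_h = (max(track$locations$time) - min(track$locations$time)) / 3600,
    total_singing_duration_h =
      if (!is.null(track$songs) && nrow(track$songs) > 0)
        (max(track$songs$end) - min(track$songs$start)) / 3600 else NA_real_,
    n_locations = nrow(track$locations),
    n_segments = if (is.null(track$segments)) 0L else nrow(track$segments),
    n_songs = if (is.null(track$songs)) 0L else nrow(track$songs),
    n_bouts = if (is.null(track$bouts)) 0L else nrow(track$bouts))
}

#' Build singer tracks from notes and locations
#'
#' Per singer present in the localization table: assemble songs, build
#' segments with trailing duty-cycles and regime classes, segment bouts at the
#' given BEC and bundle everything into a `singer_track`.
#'
#' @param notes note-event table (see [read_notes()]).
#' @param locations localization table (see [read_locations()]).
#' @param cfg an [analysis_config()].
#' @param bec bout-ending criterion in minutes (default: `cfg$default_bec`).
#' @param songs optional pre-assembled song table (skips re-assembly).
#' @return named list of `singer_track` objects.
#' @export
build_tracks <- function(notes, locations, cfg = analysis_config(), bec = NULL,
                         songs = NULL) {
  bec <- bec %||% cfg$default_bec
  songs_all <- songs %||% assemble_songs(notes, cfg)
  ids <- unique(locations$singer_id)
  tracks <- lapply(ids, function(id) {
    loc <- locations[locations$singer_id == id, , drop = FALSE]
    songs <- songs_all[songs_all$singer_id == id, , drop = FALSE]
    segs <- build_segments(loc, cfg)
    bouts <- segment_bouts(songs, bec)
    singer_track(id, loc, segs, songs, bouts, cfg)
  })
  names(tracks) <- ids
  tracks
}

#' Apply the track inclusion filter
#'
#' Keeps tracks with at least `cfg$min_locations` locations and a
#' track-duration of at least `cfg$min_track_duration` hours (boundary values
#' included), and logs the reason each excluded track was dropped.
#'
#' @param tracks list of `singer_track` objects.
#' @param cfg an [analysis_config()].
#' @return list with `tracks` (the kept list) and `exclusions` (data frame
#'   `singer_id`, `n_locations`, `track_duration_h`, `reason`).
#' @export
filter_tracks <- function(tracks, cfg = analysis_config()) {
  keep <- logical(length(tracks))
  excl <- list()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    nl <- nrow(tr$locations)
    dur <- tr$track_duration_h
    reasons <- character(0)
    if (nl < cfg$min_locations)
      reasons <- c(reasons, sprintf("only %d location(s) (< %d)", nl, cfg$min_locations))
    if (dur < cfg$min_track_duration - 1e-9)
      reasons <- c(reasons, sprintf("duration %.2f h (< %g h)", dur, cfg$min_track_duration))
    keep[i] <- length(reasons) == 0
    if (!keep[i])
      excl[[length(excl) + 1]] <- data.frame(
        singer_id = tr$singer_id, n_locations = nl, track_duration_h = dur,
        reason = paste(reasons, collapse = "; "), stringsAsFactors = FALSE)
  }
  list(tracks = tracks[keep],
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(singer_id = character(), n_locations = integer(),
                                    track_duration_h = numeric(), reason = character()))
}

#' Per-track summary listing
#'
#' One row per track: counts, track-level lengths/durations, start time and
#' season covariates, per-track summary statistics of segment speed,
#' duty-cycle and song duration, and the start regime and transition pattern.
#' This is the table written by [write_track_table()] and the per-track input
#' to the cohort statistics and additive models.
#'
#' @param tracks list of `singer_track` objects.
#' @return data frame with one row per track (zero rows for an empty list).
#' @export
track_table <- function(tracks) {
  stat5 <- function(x, prefix) {
    x <- x[is.finite(x)]
    v <- if (length(x) == 0) rep(NA_real_, 5)
         else c(mean(x), if (length(x) > 1) stats::sd(x) else NA_real_,
                stats::median(x), min(x), max(x))
    names(v) <- paste0(c("mean_", "sd_", "median_", "min_", "max_"), prefix)
    v
  }
  rows <- lapply(tracks, function(tr) {
    t0 <- min(tr$locations$time)
    segs <- tr$segments
    pattern <- if (!is.null(segs) && nrow(segs) >= 2)
      transition_pattern(segs$regime) else "undefined"
    cbind(data.frame(singer_id = tr$singer_id,
                     n_locations = nrow(tr$locations),
                     n_segments = if (is.null(segs)) 0L else nrow(segs),
                     n_songs = if (is.null(tr$songs)) 0L else nrow(tr$songs),
                     n_bouts = if (is.null(tr$bouts)) 0L else nrow(tr$bouts),
                     track_length_km = tr$track_length_km,
                     track_duration_h = tr$track_duration_h,
                     total_singing_duration_h = tr$total_singing_duration_h,
                     start_time = t0, day_of_year = epoch_doy(t0),
                     year = epoch_year(t0),
                     start_regime = if (!is.null(segs) && nrow(segs) > 0)
                       segs$regime[1] else NA_character_,
                     transition = pattern, stringsAsFactors = FALSE),
          t(stat5(segs$speed_kmh %||% numeric(0), "speed_kmh")),
          t(stat5(segs$duty_cycle_pct %||% numeric(0), "duty_cycle_pct")),
          t(stat5(song_durations(tr$songs), "song_duration_min")))
  })
  if (length(rows) == 0) {
    # header-only frame with the full column inventory
    tmpl <- c("singer_id", "n_locations", "n_segments", "n_songs", "n_bouts",
              "track_length_km", "track_duration_h", "total_singing_duration_h",
              "start_time", "day_of_year", "year", "start_regime", "transition",
              paste0(rep(c("mean_", "sd_", "median_", "min_", "max_"), 3),
                     rep(c("speed_kmh", "duty_cycle_pct", "song_duration_min"),
                         each = 5)))
    out <- as.data.frame(setNames(rep(list(logical(0)), length(tmpl)), tmpl))
    out$singer_id <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-segment listing
#'
#' Flat table of all segments across tracks with duty-cycle, regime and
#' singing-class columns — the segment-level view behind the speed x
#' duty-cycle histogram.
#' @param tracks list of `singer_track` objects.
#' @return data frame, one row per segment.
#' @export
segment_table <- function(tracks) {
  segs <- lapply(tracks, function(tr) tr$segments)
  segs <- segs[vapply(segs, function(s) !is.null(s) && nrow(s) > 0, TRUE)]
  if (length(segs) == 0)
    return(data.frame(singer_id = character(), t_start = numeric(),
                      t_end = numeric(), distance_km = numeric(),
                      elapsed_h = numeric(), speed_kmh = numeric(),
                      duty_cycle_pct = numeric(), window_used_min = numeric(),
                      regime = character(), dc_class = character()))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
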