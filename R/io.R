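# CSV readers/writers for the note-event, localization and per-track tables.
# Readers are schema-tolerant: columns are mapped by name and extra columns are
# ignored, so per-track listings exported by other tools can be ingested as
# long as the named fields are present.

pick_column <- function(df, candidates, what, path) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit) == 0)
    stop("'", path, "': no ", what, " column (looked for ",
         paste(candidates, collapse = ", "), ")", call. = FALSE)
  df[[hit[1]]]
}

#' Read a note-event table
#'
#' Reads per-singer 20 Hz note detections from CSV. Required columns (by name,
#' extras ignored): a singer identifier (`singer_id`/`singer`), a start time
#' (`start`, `start_s`, `epoch_s` in seconds, or `start_iso8601`/`start_time`
#' as ISO-8601 UTC), and a duration in seconds (`duration_s`/`duration`).
#'
#' Rows are validated (positive durations, parseable times) and sorted by start
#' time within each singer; overlapping notes for one singer are rejected,
#' since one animal cannot emit two 20 Hz notes at once.
#'
#' @param path CSV file.
#' @return data frame with columns `singer_id`, `start` (epoch seconds, UTC)
#'   and `duration` (seconds), sorted by singer then start.
#' @seealso [assemble_songs()]
#' @export
read_notes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  singer <- as.character(pick_column(df, c("singer_id", "singer", "id"), "singer id", path))
  start_raw <- pick_column(df, c("start", "start_s", "epoch_s", "start_iso8601", "start_time"),
                           "start time", path)
  duration <- pick_column(df, c("duration_s", "duration", "dur_s"), "duration", path)
  start <- parse_time_utc(start_raw)
  bad <- which(!is.finite(start))
  if (length(bad) > 0)
    stop("'", path, "': unparseable start time in row ", bad[1], call. = FALSE)
  duration <- as.numeric(duration)
  bad <- which(!is.finite(duration) | duration <= 0)
  if (length(bad) > 0)
    stop("'", path, "': non-positive or missing duration in row ", bad[1], call. = FALSE)
  out <- data.frame(singer_id = singer, start = start, duration = duration,
                    stringsAsFactors = FALSE)
  row_id <- seq_len(nrow(out))
  ord <- order(out$singer_id, out$start)
  out <- out[ord, , drop = FALSE]
  row_id <- row_id[ord]
  # overlap check within each singer on the sorted stream
  for (d in split(seq_len(nrow(out)), out$singer_id)) {
    if (length(d) < 2) next
    ends <- out$start[d] + out$duration[d]
    ov <- which(out$start[d][-1] < ends[-length(d)] - 1e-9)
    if (length(ov) > 0)
      stop("'", path, "': overlapping notes for singer '", out$singer_id[d[1]],
           "' (rows ", row_id[d[ov[1]]], " and ", row_id[d[ov[1] + 1]], ")",
           call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a note-event table
#' @param notes data frame as returned by [read_notes()] or the simulator.
#' @param path output CSV file.
#' @export
write_notes <- function(notes, path) {
  utils::write.csv(notes[, c("singer_id", "start", "duration"), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a localization table
#'
#' Reads timestamped singer positions from CSV. Required columns: singer id,
#' time (`time`, `time_s`, `epoch_s` or `time_iso8601`), and either `lat`/`lon`
#' (WGS84 decimal degrees) or `x_km`/`y_km` (planar kilometre grid, used by
#' synthetic scenarios). Times must be strictly increasing within each singer;
#' duplicate or out-of-order timestamps are rejected.
#'
#' @param path CSV file.
#' @return data frame with columns `singer_id`, `time` (epoch seconds) and
#'   either `lat`,`lon` or `x_km`,`y_km`.
#' @export
read_locations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  singer <- as.character(pick_column(df, c("singer_id", "singer", "id"), "singer id", path))
  time_raw <- pick_column(df, c("time", "time_s", "epoch_s", "time_iso8601", "start_time"),
                          "time", path)
  tm <- parse_time_utc(time_raw)
  bad <- which(!is.finite(tm))
  if (length(bad) > 0)
    stop("'", path, "': unparseable time in row ", bad[1], call. = FALSE)
  planar <- all(c("x_km", "y_km") %in% names(df))
  if (planar) {
    out <- data.frame(singer_id = singer, time = tm,
                      x_km = as.numeric(df$x_km), y_km = as.numeric(df$y_km),
                      stringsAsFactors = FALSE)
    if (anyNA(out$x_km) || anyNA(out$y_km))
      stop("'", path, "': missing planar coordinates", call. = FALSE)
  } else {
    lat <- as.numeric(pick_column(df, c("lat", "latitude"), "latitude", path))
    lon <- as.numeric(pick_column(df, c("lon", "long", "longitude"), "longitude", path))
    bad <- which(!is.finite(lat) | abs(lat) > 90)
    if (length(bad) > 0)
      stop("'", path, "': latitude out of range [-90, 90] in row ", bad[1], call. = FALSE)
    bad <- which(!is.finite(lon) | abs(lon) > 180)
    if (length(bad) > 0)
      stop("'", path, "': longitude out of range [-180, 180] in row ", bad[1], call. = FALSE)
    out <- data.frame(singer_id = singer, time = tm, lat = lat, lon = lon,
                      stringsAsFactors = FALSE)
  }
  # strictly increasing time within singer, in file order
  for (d in split(seq_len(nrow(out)), out$singer_id)) {
    dt <- diff(out$time[d])
    bad <- which(dt <= 0)
    if (length(bad) > 0)
      stop("'", path, "': times not strictly increasing for singer '",
           out$singer_id[d[1]], "' at row ", d[bad[1] + 1], call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a localization table
#' @param locations data frame as returned by [read_locations()].
#' @param path output CSV file.
#' @export
write_locations <- function(locations, path) {
  utils::write.csv(locations, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-track summary listing
#'
#' One row per singer track with counts, track-level durations and lengths and
#' per-track summary statistics (mean/sd/median/min/max) of segment speed,
#' duty-cycle and song duration. This mirrors the per-track listings published
#' as supplementary material in tracking studies and round-trips through
#' [read_track_table()].
#'
#' @param tracks list of `singer_track` objects (see [build_tracks()]) or a
#'   data frame already in track-table form.
#' @param path output CSV file.
#' @return the path, invisibly. An empty track list yields a header-only file.
#' @export
write_track_table <- function(tracks, path) {
  df <- if (is.data.frame(tracks)) tracks else track_table(tracks)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-track summary listing
#'
#' Schema-tolerant counterpart of [write_track_table()]: columns are matched by
#' name and unknown columns are ignored, so externally produced per-track
#' listings can be read as long as the named fields are present.
#' @param path CSV file.
#' @return data frame in track-table form.
#' @export
read_track_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("singer_id" %in% names(df)) df$singer_id <- as.character(df$singer_id)
  df
}
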