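# Song assembly: turn a singer's 20 Hz note stream into songs.

#' Assemble songs from 20 Hz note events
#'
#' Scans each singer's time-ordered note stream left to right and accumulates
#' a candidate song while the inter-note-interval (start-to-start of successive
#' notes) does not exceed `cfg$note_break` (30 s by default: an interval of
#' exactly 30 s continues the song, anything greater breaks it). Candidates
#' with at least `cfg$min_notes` notes become songs; shorter runs — isolated
#' notes or pairs — are discarded. Song duration runs from the start of the
#' first note to the end of the last note.
#'
#' The 9-20 s band typical of North Atlantic fin whale song is not an exclusion
#' rule: intervals in (20, 30] s keep a song growing, and the fraction of
#' intervals inside the typical band is reported per song as a regularity
#' diagnostic (`frac_typical_ini`).
#'
#' @param notes data frame with columns `singer_id`, `start` (epoch seconds)
#'   and `duration` (seconds); see [read_notes()].
#' @param cfg an [analysis_config()].
#' @return data frame with one row per song: `singer_id`, `start`, `end`
#'   (epoch seconds), `note_count`, `duration_s` and `frac_typical_ini`,
#'   ordered by singer and start time. Empty input gives an empty frame.
#' @examples
#' notes <- data.frame(singer_id = "A", start = c(0, 12, 24), duration = 1)
#' assemble_songs(notes)  # one song, 0-25 s
#' @export
assemble_songs <- function(notes, cfg = analysis_config()) {
  empty <- data.frame(singer_id = character(), start = numeric(),
                      end = numeric(), note_count = integer(),
                      duration_s = numeric(), frac_typical_ini = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(notes) || nrow(notes) == 0) return(empty)
  ord <- order(notes$singer_id, notes$start)
  start <- notes$start[ord]
  dur <- notes$duration[ord]
  singer <- notes$singer_id[ord]
  pieces <- lapply(split(seq_along(start), singer), function(ix) {
    s <- start[ix]; d <- dur[ix]
    n <- length(ix)
    gap <- if (n > 1) diff(s) else numeric(0)
    brk <- gap > cfg$note_break
    grp <- cumsum(c(TRUE, brk))
    counts <- tabulate(grp)
    first <- which(c(TRUE, brk))
    last <- c(first[-1] - 1L, n)
    # within-group inter-note-intervals in the typical band, per group
    within <- !brk
    typ_n <- rep(0, length(counts))
    if (any(within)) {
      typ <- tapply((gap >= cfg$ini_min & gap <= cfg$ini_max)[within],
                    grp[-1][within], sum)
      typ_n[as.integer(names(typ))] <- typ
    }
    keep <- counts >= cfg$min_notes
    if (!any(keep)) return(NULL)
    st <- s[first[keep]]
    en <- s[last[keep]] + d[last[keep]]
    data.frame(singer_id = singer[ix[1]], start = st, end = en,
               note_count = counts[keep], duration_s = en - st,
               frac_typical_ini = typ_n[keep] / (counts[keep] - 1),
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0) return(empty)
  out <- do.call(rbind, pieces)
  out <- out[order(out$singer_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Song durations in minutes
#'
#' @param songs song table from [assemble_songs()].
#' @return numeric vector, one duration (minutes) per song.
#' @export
song_durations <- function(songs) {
  if (is.null(songs) || nrow(songs) == 0) return(numeric(0))
  songs$duration_s / 60
}

#' Inter-song-intervals in minutes
#'
#' For each singer, the silence from the end of one song to the start of the
#' next. These intervals — short within-bout rests and long between-bout gaps —
#' are the raw material of the bout-ending-criterion analysis.
#'
#' @param songs song table from [assemble_songs()] (may cover many singers;
#'   intervals are computed within singer and pooled).
#' @return numeric vector of intervals in minutes; singers with fewer than two
#'   songs contribute nothing.
#' @seealso [interval_log_frequency()], [segment_bouts()]
#' @export
inter_song_intervals <- function(songs) {
  if (is.null(songs) || nrow(songs) < 2) return(numeric(0))
  unlist(lapply(split(songs, songs$singer_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    if (n < 2) return(numeric(0))
    (d$start[-1] - d$end[-n]) / 60
  }), use.names = FALSE)
}
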