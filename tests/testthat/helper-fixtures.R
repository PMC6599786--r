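# small in-code fixtures shared across the test files

make_notes <- function(starts, duration = 1, singer = "A") {
  data.frame(singer_id = rep_len(singer, length(starts)), start = starts,
             duration = rep_len(duration, length(starts)),
             stringsAsFactors = FALSE)
}

make_songs <- function(starts_min, ends_min, singer = "A") {
  data.frame(singer_id = singer, start = starts_min * 60, end = ends_min * 60,
             stringsAsFactors = FALSE)
}

make_locations <- function(times_h, lat = NULL, lon = NULL, x_km = NULL,
                           y_km = NULL, singer = "A") {
  d <- data.frame(singer_id = singer, time = times_h * 3600,
                  stringsAsFactors = FALSE)
  if (!is.null(lat)) { d$lat <- lat; d$lon <- lon }
  if (!is.null(x_km)) { d$x_km <- x_km; d$y_km <- y_km }
  d
}

# hand-written haversine, independent of the geosphere-backed implementation
oracle_haversine_km <- function(lat1, lon1, lat2, lon2, r = 6371) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# brute-force song scanner: walks the note list and grows a run while the
# start-to-start interval stays within the break, then applies the minimum
# note count — mechanically different from the vectorized implementation
oracle_songs <- function(starts, durations, min_notes = 3, note_break = 30) {
  n <- length(starts)
  out <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && (starts[j + 1] - starts[j]) <= note_break) j <- j + 1
    if (j - i + 1 >= min_notes)
      out[[length(out) + 1]] <- c(start = starts[i],
                                  end = starts[j] + durations[j],
                                  n = j - i + 1)
    i <- j + 1
  }
  if (length(out) == 0) return(NULL)
  as.data.frame(do.call(rbind, out))
}

# 1-second rasterization of the duty-cycle window
oracle_duty_cycle <- function(win_start, win_end, song_starts, song_ends) {
  mids <- seq(win_start + 0.5, win_end - 0.5, by = 1)
  inside <- rep(FALSE, length(mids))
  for (k in seq_along(song_starts))
    inside <- inside | (mids >= song_starts[k] & mids < song_ends[k])
  100 * mean(inside)
}

# a small cohort for pipeline-level tests
tiny_cohort <- function(n = 8, seed = 42) {
  generate_cohort(n_tracks = n, seed = seed,
                  duration_range_h = c(6, 20))
}
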