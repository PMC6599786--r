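cfg_planar <- analysis_config(planar = TRUE)

test_that("segment speeds are distance over elapsed time", {
  locs <- make_locations(c(0, 1), x_km = c(0, 10), y_km = c(0, 0))
  segs <- build_segments(locs, cfg_planar)
  expect_equal(segs$distance_km, 10)
  expect_equal(segs$speed_kmh, 10)

  # one degree of longitude at 60 N, four hours apart
  locs2 <- make_locations(c(0, 4), lat = c(60, 60), lon = c(-30, -29))
  segs2 <- build_segments(locs2)
  expect_equal(segs2$distance_km,
               oracle_haversine_km(60, -30, 60, -29), tolerance = 1e-9)
  expect_equal(segs2$distance_km, 55.6, tolerance = 0.01)
  expect_equal(segs2$speed_kmh, 13.9, tolerance = 0.01)

  # n locations produce n-1 segments
  n <- 7
  locs3 <- make_locations(0:(n - 1), x_km = cumsum(runif(n, 5, 15)),
                          y_km = rep(0, n))
  expect_equal(nrow(build_segments(locs3, cfg_planar)), n - 1)

  dup <- make_locations(c(0, 0), x_km = c(0, 5), y_km = c(0, 0))
  expect_error(build_segments(dup, cfg_planar), "elapsed")
})

test_that("distance is symmetric and speeds are finite and nonnegative", {
  set.seed(4)
  lat <- runif(20, -60, 60); lon <- runif(20, -180, 180)
  d1 <- great_circle_km(lat[1:10], lon[1:10], lat[11:20], lon[11:20])
  d2 <- great_circle_km(lat[11:20], lon[11:20], lat[1:10], lon[1:10])
  expect_equal(d1, d2)
  expect_true(all(is.finite(d1) & d1 >= 0))
})

test_that("trailing duty-cycle uses interval intersection and records the window", {
  # segment 0..2 h; window is its last 30 min
  segs <- build_segments(make_locations(c(0, 2), x_km = c(0, 10), y_km = c(0, 0)),
                         cfg_planar)
  # song covering the whole window
  full <- data.frame(singer_id = "A", start = 3600, end = 7200)
  expect_equal(segment_duty_cycle(segs, full, cfg_planar)$duty_cycle_pct, 100)
  # 15 min of song inside the 30 min window
  half <- data.frame(singer_id = "A", start = 7200 - 900, end = 7200)
  got <- segment_duty_cycle(segs, half, cfg_planar)
  expect_equal(got$duty_cycle_pct, 50)
  expect_equal(got$window_used_min, 30)
  # no songs at all
  expect_equal(segment_duty_cycle(segs, full[0, ], cfg_planar)$duty_cycle_pct, 0)

  # a segment shorter than the window uses its full span
  short <- build_segments(make_locations(c(0, 1 / 3), x_km = c(0, 10), y_km = c(0, 0)),
                          cfg_planar)
  got2 <- segment_duty_cycle(short, data.frame(singer_id = "A", start = 0, end = 600),
                             cfg_planar)
  expect_equal(got2$window_used_min, 20)
  expect_equal(got2$duty_cycle_pct, 50)
})

test_that("duty-cycle matches a 1-second rasterization oracle", {
  # song times quantized to whole seconds (the raster resolution) so the
  # rasterization is exact and any discrepancy is an interval-arithmetic bug
  set.seed(8)
  for (rep in 1:60) {
    t_end <- round(runif(1, 3 * 3600, 10 * 3600))
    t_start <- t_end - round(runif(1, 0.6, 4) * 3600)
    segs <- data.frame(singer_id = "A", t_start = t_start, t_end = t_end,
                       distance_km = 1, elapsed_h = (t_end - t_start) / 3600,
                       speed_kmh = 1)
    ns <- sample(0:8, 1)
    durs <- round(runif(ns, 60, 1200))
    gaps <- round(runif(ns, 10, 2000))
    starts <- t_start - 3600 + cumsum(gaps + c(0, durs[-length(durs)]))
    songs <- data.frame(singer_id = rep("A", ns), start = starts,
                        end = starts + durs)
    got <- segment_duty_cycle(segs, songs, cfg_planar)
    ws <- max(t_end - 1800, t_start)
    want <- oracle_duty_cycle(ws, t_end, songs$start, songs$end)
    expect_lt(abs(got$duty_cycle_pct - want), 0.1)
  }
})

test_that("fractional song overlap is computed exactly", {
  segs <- data.frame(singer_id = "A", t_start = 0, t_end = 3600,
                     distance_km = 1, elapsed_h = 1, speed_kmh = 1)
  # 123.45 s of overlap inside the 1800 s window starting at 1800
  songs <- data.frame(singer_id = "A", start = 1700, end = 1923.45)
  got <- segment_duty_cycle(segs, songs, cfg_planar)$duty_cycle_pct
  expect_equal(got, 100 * 123.45 / 1800, tolerance = 1e-12)
})

test_that("duty-cycle is invariant under time translation", {
  segs <- data.frame(singer_id = "A", t_start = 0, t_end = 7200,
                     distance_km = 5, elapsed_h = 2, speed_kmh = 2.5)
  songs <- data.frame(singer_id = "A", start = c(5000, 6500), end = c(5900, 7100))
  base <- segment_duty_cycle(segs, songs, cfg_planar)$duty_cycle_pct
  for (shift in c(-1e6, 12345, 1e9)) {
    segs2 <- transform(segs, t_start = t_start + shift, t_end = t_end + shift)
    songs2 <- transform(songs, start = start + shift, end = end + shift)
    expect_equal(segment_duty_cycle(segs2, songs2, cfg_planar)$duty_cycle_pct,
                 base, tolerance = 1e-9)
  }
})

test_that("classification thresholds are inclusive at the boundary", {
  cfg <- analysis_config()
  expect_equal(classify_duty_cycle(c(88, 48, 70, 69.999), cfg),
               c("robust", "intermittent", "robust", "intermittent"))
  expect_equal(classify_speed_regime(c(6.9, 7, 14.1), cfg),
               c("slow", "fast", "fast"))
})

test_that("transition patterns summarize the regime sequence", {
  expect_equal(transition_pattern(c("slow", "slow", "slow", "slow")), "stayed_slow")
  expect_equal(transition_pattern(c("fast", "fast")), "stayed_fast")
  expect_equal(transition_pattern(c("slow", "slow", "fast", "fast")), "switched_to_fast")
  expect_equal(transition_pattern(c("fast", "slow")), "switched_to_slow")
  expect_equal(transition_pattern(c("slow", "fast", "slow", "fast")), "alternating")
  expect_warning(out <- transition_pattern("slow"), "undefined")
  expect_equal(out, "undefined")
})

test_that("track summaries recompute lengths and durations", {
  locs <- make_locations(c(0, 2, 4), x_km = c(0, 10, 20), y_km = 0)
  notes <- make_notes(seq(0, 3600, by = 12))
  cfg <- cfg_planar
  tracks <- build_tracks(notes, locs, cfg)
  tr <- tracks[["A"]]
  expect_equal(tr$track_length_km, 20)
  expect_equal(tr$track_duration_h, 4)
  # single-bout track: total-singing-duration equals the bout duration
  expect_equal(nrow(tr$bouts), 1)
  expect_equal(tr$total_singing_duration_h, tr$bouts$duration_s / 3600)
  s <- track_summaries(tr)
  expect_equal(unname(s["track_length_km"]), tr$track_length_km)
  expect_equal(unname(s["n_locations"]), 3)
  # segment elapsed times partition the track duration
  expect_equal(sum(tr$segments$elapsed_h), tr$track_duration_h)
})

test_that("the inclusion filter keeps >=3 locations and >=1 h, logging exclusions", {
  cfg <- cfg_planar
  mk <- function(times_h, id) {
    locs <- make_locations(times_h, x_km = seq_along(times_h) * 10,
                           y_km = 0, singer = id)
    singer_track(id, locs, build_segments(locs, cfg),
                 assemble_songs(make_notes(numeric(0)), cfg),
                 segment_bouts(assemble_songs(make_notes(numeric(0)), cfg), 35),
                 cfg)
  }
  tracks <- list(mk(c(0, 2), "two_locs"),
                 mk(c(0, 0.25, 0.5), "half_hour"),
                 mk(c(0, 0.5, 1), "boundary"),
                 mk(c(0, 1, 2, 3), "good"))
  res <- filter_tracks(tracks, cfg)
  kept <- vapply(res$tracks, function(t) t$singer_id, "")
  expect_setequal(kept, c("boundary", "good"))
  expect_equal(nrow(res$exclusions), 2)
  expect_match(res$exclusions$reason[res$exclusions$singer_id == "two_locs"],
               "location")
  expect_match(res$exclusions$reason[res$exclusions$singer_id == "half_hour"],
               "duration")
})

test_that("window_used never exceeds the configured window", {
  coh <- tiny_cohort(4)
  cfg <- cfg_planar
  tracks <- build_tracks(coh$notes, coh$locations, cfg)
  segs <- segment_table(tracks)
  expect_true(all(segs$window_used_min <= 30 + 1e-9))
  long <- segs$elapsed_h >= 0.5
  expect_equal(segs$window_used_min[long], rep(30, sum(long)))
  expect_true(all(segs$duty_cycle_pct >= 0 & segs$duty_cycle_pct <= 100 + 1e-9))
})
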