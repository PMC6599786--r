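jan_epoch <- as.numeric(ISOdatetime(2007, 1, 10, 0, 0, 0, tz = "UTC"))

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_singer(behavior_params(), 10, seed = 5, start_time = jan_epoch)
  b <- simulate_singer(behavior_params(), 10, seed = 5, start_time = jan_epoch)
  expect_identical(a$notes, b$notes)
  expect_identical(a$path, b$path)

  c1 <- generate_cohort(n_tracks = 3, seed = 77)
  c2 <- generate_cohort(n_tracks = 3, seed = 77)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$locations, c2$locations)
  # different seeds give different data
  c3 <- generate_cohort(n_tracks = 3, seed = 78)
  expect_false(identical(c1$notes, c3$notes))
})

test_that("slow-only singers realize the configured high duty-cycle band", {
  p <- behavior_params(seasonal_amp = 0)   # isolate the duty target from season
  sim <- simulate_singer(p, 12, seed = 31, slow_only = TRUE,
                         start_time = jan_epoch)
  songs <- assemble_songs(sim$notes)
  # trailing 30-min windows sampled through the track interior
  ends <- seq(2 * 3600, 11 * 3600, by = 1800)
  segs <- data.frame(singer_id = "Fin-001", t_start = ends - 3600,
                     t_end = jan_epoch + ends, distance_km = 1,
                     elapsed_h = 1, speed_kmh = 1)
  segs$t_start <- segs$t_end - 3600
  dc <- segment_duty_cycle(segs, songs, analysis_config())$duty_cycle_pct
  # relaxed surfacing rests pull a tail of windows below the [75, 90] target
  expect_gt(mean(dc), 70)
  expect_lt(mean(dc), 92)
  expect_gt(mean(dc >= 65), 0.8)
})

test_that("silent-fast singers emit no songs during fast dwells", {
  p <- behavior_params(p_start_slow = 0)   # start fast
  sim <- simulate_singer(p, 6, seed = 8, slow_only = FALSE, silent_fast = TRUE)
  fast <- sim$states[sim$states$state == "fast", ]
  songs <- assemble_songs(sim$notes)
  for (i in seq_len(nrow(fast))) {
    t0 <- fast$t0_h[i] * 3600; t1 <- fast$t1_h[i] * 3600
    ov <- sum(pmax(0, pmin(songs$end, t1) - pmax(songs$start, t0)))
    # note-level jitter can spill a song edge by under a second
    expect_lt(ov, 2)
  }
})

test_that("decimation enforces the minimum location separation", {
  # straight path at 5 km/h sampled hourly: locations every 2 h
  path <- data.frame(time = (0:10) * 3600, x_km = (0:10) * 5, y_km = 0)
  dec <- decimate_locations(path, 10)
  expect_equal(dec$time / 3600, seq(0, 10, by = 2))

  sim <- simulate_singer(behavior_params(), 15, seed = 3, start_time = jan_epoch)
  dec2 <- decimate_locations(sim$path, 10)
  if (nrow(dec2) >= 2) {
    d <- sqrt(diff(dec2$x_km)^2 + diff(dec2$y_km)^2)
    expect_true(all(d >= 10 - 1e-9))
    # chord distances never exceed the true path length between fixes
    path_len <- sum(sqrt(diff(sim$path$x_km)^2 + diff(sim$path$y_km)^2))
    seg_sum <- sum(d)
    expect_lte(seg_sum, path_len + 1e-9)
  }
})

test_that("song durations decrease with state speed by construction", {
  p <- behavior_params(seasonal_amp = 0, song_sdlog = 0.05)
  slow <- simulate_singer(p, 10, seed = 41, slow_only = TRUE,
                          start_time = jan_epoch)
  fastp <- behavior_params(seasonal_amp = 0, song_sdlog = 0.05,
                           p_start_slow = 0, slow_dwell_mean_h = 0.0001,
                           fast_dwell_mean_h = 100)
  fast <- simulate_singer(fastp, 10, seed = 42, silent_fast = FALSE)
  slow_d <- mean(song_durations(assemble_songs(slow$notes)))
  fast_d <- mean(song_durations(assemble_songs(fast$notes)))
  expect_gt(slow_d, fast_d)
})

test_that("cohorts carry the configured singer mix and run end-to-end at n = 1", {
  coh <- generate_cohort(n_tracks = 60, seed = 19)
  expect_equal(nrow(coh$truth), 60)
  expect_equal(length(unique(coh$notes$singer_id)) <= 60, TRUE)
  frac_slow_only <- mean(coh$truth$slow_only)
  expect_gt(frac_slow_only, 0.15)
  expect_lt(frac_slow_only, 0.5)
  # seasonal weighting: most tracks in the singing season
  doy <- coh$truth$day_of_year
  in_season <- doy >= 258 | doy <= 74
  expect_gt(mean(in_season), 0.55)

  one <- generate_cohort(n_tracks = 1, seed = 4, duration_range_h = c(10, 20))
  an <- suppressMessages(run_pipeline(one$notes, one$locations,
                                      analysis_config(planar = TRUE)))
  expect_s3_class(an, "finsong_analysis")
  expect_equal(length(an$tracks), 1)
})

test_that("invalid behaviour parameters are rejected", {
  expect_error(behavior_params(rest_range_min = c(10, 3)), "ordered")
  expect_error(behavior_params(p_slow_only = 1.4), "probability")
  expect_error(behavior_params(step_min = 0), "positive")
  expect_error(behavior_params(seasonal_amp = 1.2), "seasonal_amp")
  expect_error(simulate_singer(behavior_params(), duration_h = -2), "positive")
})

test_that("planar to geographic conversion preserves local distances", {
  path <- data.frame(time = c(0, 3600), x_km = c(0, 10), y_km = c(0, 0))
  geo <- planar_to_latlon(path, 50, -30)
  d <- great_circle_km(geo$lat[1], geo$lon[1], geo$lat[2], geo$lon[2])
  expect_equal(d, 10, tolerance = 0.01)
})
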