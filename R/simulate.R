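# Synthetic singer simulator: a two-state (slow/high-duty-cycle vs
# fast/low-duty-cycle) semi-Markov behaviour model driving a correlated random
# walk, with songs of regularly spaced 20 Hz notes, 3-10 min within-bout
# rests, inter-bout silences of at least the bout-ending criterion, and
# singing that decreases with swimming speed. The generator gives every
# pipeline stage a known ground truth.

#' Behaviour parameters for the synthetic singer
#'
#' Defaults emulate the qualitative structure of North Atlantic fin whale
#' singer tracks: a slow singing state (lognormal speeds, median
#' ~5.5 km/h) with a 75-90% target duty-cycle, a fast transit state (median
#' ~13 km/h) in which singing is fragmented (shortened songs, elevated rest
#' rate) or — for a per-singer subset — absent, song durations that decrease
#' with speed, within-bout rests of 3-10 min, inter-bout gaps of at least
#' 35 min, and a September-February seasonal peak in singing.
#'
#' @param slow_speed_median_kmh,slow_speed_sdlog lognormal path-speed
#'   distribution of the slow singing state.
#' @param fast_speed_median_kmh,fast_speed_sdlog same for the fast transit
#'   state.
#' @param slow_duty_range,fast_duty_range per-state target duty-cycle ranges
#'   (percent).
#' @param slow_dwell_mean_h,fast_dwell_mean_h mean state dwell times (hours,
#'   exponential dwell distributions truncated below at `min_dwell_h`).
#' @param min_dwell_h minimum dwell time (hours).
#' @param turn_sd_slow,turn_sd_fast heading persistence of the correlated
#'   random walk: s.d. (radians) of the per-step turning angle in each state
#'   (slow singers meander, fast transits hold course).
#' @param song_base_min,song_speed_slope,song_sdlog,song_min_min song-duration
#'   model: duration in minutes is
#'   `(song_base_min - song_speed_slope * speed) * season * lognormal-noise`,
#'   floored at `song_min_min`.
#' @param rest_range_min within-bout rest range (minutes) in the slow state;
#'   realized rests decay exponentially from the range minimum with mean set
#'   by the duty-cycle target, truncated at the range maximum.
#' @param fast_rest_range_min rest range in the fast state (same 3-10 min
#'   band by default: fragmented fast singing comes from an elevated rest
#'   rate — short songs, frequent rests — not from longer silences).
#' @param fast_song_factor multiplicative shortening of songs in the fast
#'   state.
#' @param travel_gap_p,travel_gap_min_min,travel_gap_mean_min occasional
#'   intermediate silences ("travel gaps", `min + Exp(mean)` minutes) longer
#'   than a breathing rest but typically shorter than a bout break; they give
#'   the interval distribution the continuous slow tail seen in real interval
#'   data.
#' @param interbout_gap_min_min,interbout_gap_mean_min inter-bout silences are
#'   `min + Exp(mean)` minutes, so every gap is at least the default BEC.
#' @param seasonal_amp,seasonal_peak_doy cosine seasonal modulation (relative
#'   amplitude, peak day-of-year) applied to song duration and duty-cycle
#'   targets.
#' @param ini_range_s per-song inter-note-interval is drawn uniformly from
#'   this range (seconds) and held fixed within the song, with small per-note
#'   jitter.
#' @param note_duration_s 20 Hz note duration (seconds).
#' @param p_slow_only probability a singer never enters the fast state.
#' @param p_silent_fast probability (for singers that do go fast) that the
#'   fast state is silent rather than fragmented singing.
#' @param p_start_slow probability a track starts in the slow state.
#' @param step_min movement-integration step (minutes).
#' @param speed_jitter_sdlog within-dwell per-step speed jitter (lognormal
#'   s.d.).
#' @return object of class `behavior_params` (validated named list).
#' @export
behavior_params <- function(slow_speed_median_kmh = 5.5,
                            slow_speed_sdlog = 0.35,
                            fast_speed_median_kmh = 12.5,
                            fast_speed_sdlog = 0.25,
                            slow_duty_range = c(75, 90),
                            fast_duty_range = c(10, 30),
                            slow_dwell_mean_h = 5,
                            fast_dwell_mean_h = 1.5,
                            min_dwell_h = 0.75,
                            turn_sd_slow = 0.35,
                            turn_sd_fast = 0.12,
                            song_base_min = 24,
                            song_speed_slope = 0.9,
                            song_sdlog = 0.35,
                            song_min_min = 0.8,
                            rest_range_min = c(3, 10),
                            fast_rest_range_min = c(3, 10),
                            fast_song_factor = 0.14,
                            travel_gap_p = 0.02,
                            travel_gap_min_min = 12,
                            travel_gap_mean_min = 12,
                            interbout_gap_min_min = 35,
                            interbout_gap_mean_min = 30,
                            seasonal_amp = 0.12,
                            seasonal_peak_doy = 350,
                            ini_range_s = c(10, 15),
                            note_duration_s = 1,
                            p_slow_only = 0.31,
                            p_silent_fast = 0.55,
                            p_start_slow = 0.57,
                            step_min = 5,
                            speed_jitter_sdlog = 0.08) {
  p <- as.list(environment())
  for (f in c("slow_duty_range", "fast_duty_range", "rest_range_min",
              "fast_rest_range_min", "ini_range_s"))
    if (length(p[[f]]) != 2 || p[[f]][1] > p[[f]][2] || any(p[[f]] < 0))
      stop("parameter '", f, "' must be an ordered non-negative range", call. = FALSE)
  for (f in c("slow_speed_median_kmh", "fast_speed_median_kmh",
              "slow_dwell_mean_h", "fast_dwell_mean_h", "min_dwell_h",
              "song_base_min", "song_min_min", "note_duration_s", "step_min",
              "interbout_gap_mean_min"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || p[[f]] <= 0)
      stop("parameter '", f, "' must be a single positive number", call. = FALSE)
  for (f in c("p_slow_only", "p_silent_fast", "p_start_slow"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop("parameter '", f, "' must be a probability", call. = FALSE)
  if (p$seasonal_amp < 0 || p$seasonal_amp >= 1)
    stop("seasonal_amp must be in [0, 1)", call. = FALSE)
  structure(p, class = "behavior_params")
}

season_multiplier <- function(doy, params) {
  1 + params$seasonal_amp * cos(2 * pi * (doy - params$seasonal_peak_doy) / 365.25)
}

#' Simulate one singer
#'
#' Alternates slow-singing and fast-transit dwells (semi-Markov, exponential
#' dwell times), moves the singer by a correlated random walk with per-state
#' speeds and heading persistence, and emits songs whose duration decreases
#' with the current speed, separated by within-bout rests set from the state's
#' target duty-cycle (clipped to the configured rest range). Multi-bout
#' singers have silent inter-bout gaps of at least
#' `interbout_gap_min_min` carved out of the song sequence. Songs are realized
#' as notes with a per-song inter-note-interval drawn from `ini_range_s`.
#'
#' @param params a [behavior_params()].
#' @param duration_h track duration to simulate (hours).
#' @param seed optional integer seed (the run is deterministic given the
#'   seed).
#' @param singer_id identifier stamped on the outputs.
#' @param start_time epoch seconds (UTC) of the track start; supplies the
#'   day-of-year for the seasonal modulation.
#' @param slow_only if `TRUE` the singer never leaves the slow state.
#' @param silent_fast if `TRUE` the singer is silent (rather than singing
#'   fragmented songs) in the fast state.
#' @param n_bouts number of singing bouts (1 = no inter-bout gap).
#' @return list with `path` (data frame `time`, `x_km`, `y_km`, `state`,
#'   `speed_kmh` at `step_min` resolution), `notes` (note-event table),
#'   `songs` (true emitted songs), `states` (dwell table `state`, `t0_h`,
#'   `t1_h`) and the inputs (`singer_id`, `start_time`, `duration_h`).
#' @export
simulate_singer <- function(params = behavior_params(), duration_h, seed = NULL,
                            singer_id = "Fin-001", start_time = 0,
                            slow_only = FALSE, silent_fast = TRUE,
                            n_bouts = 1L) {
  stopifnot(inherits(params, "behavior_params"))
  if (!is.numeric(duration_h) || duration_h <= 0)
    stop("duration_h must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # --- state dwell plan -----------------------------------------------------
  first_slow <- slow_only || stats::runif(1) < params$p_start_slow
  st <- character(0); t0 <- numeric(0)
  tcur <- 0; cur <- if (first_slow) "slow" else "fast"
  while (tcur < duration_h) {
    mean_dwell <- if (cur == "slow") params$slow_dwell_mean_h else params$fast_dwell_mean_h
    dwell <- if (slow_only) duration_h + 1 else
      max(params$min_dwell_h, stats::rexp(1, 1 / mean_dwell))
    st <- c(st, cur); t0 <- c(t0, tcur)
    tcur <- tcur + dwell
    cur <- if (cur == "slow") "fast" else "slow"
  }
  states <- data.frame(state = st, t0_h = t0,
                       t1_h = c(t0[-1], duration_h), stringsAsFactors = FALSE)
  states <- states[states$t1_h > states$t0_h, , drop = FALSE]

  # --- movement: correlated random walk at step_min resolution --------------
  dt_h <- params$step_min / 60
  nstep <- max(1L, ceiling(duration_h / dt_h))
  tmid_h <- (seq_len(nstep) - 0.5) * dt_h
  dwell_ix <- findInterval(tmid_h, states$t0_h)
  state_step <- states$state[dwell_ix]
  base_speed <- vapply(seq_len(nrow(states)), function(i) {
    if (states$state[i] == "slow")
      stats::rlnorm(1, log(params$slow_speed_median_kmh), params$slow_speed_sdlog)
    else
      stats::rlnorm(1, log(params$fast_speed_median_kmh), params$fast_speed_sdlog)
  }, 0)
  speed_step <- base_speed[dwell_ix] *
    exp(stats::rnorm(nstep, 0, params$speed_jitter_sdlog))
  turn_sd <- ifelse(state_step == "slow", params$turn_sd_slow, params$turn_sd_fast)
  heading <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(nstep, 0, turn_sd))
  dx <- speed_step * dt_h * cos(heading)
  dy <- speed_step * dt_h * sin(heading)
  path <- data.frame(time = start_time + c(0, seq_len(nstep)) * dt_h * 3600,
                     x_km = c(0, cumsum(dx)), y_km = c(0, cumsum(dy)),
                     state = c(state_step[1], state_step),
                     speed_kmh = c(speed_step[1], speed_step),
                     stringsAsFactors = FALSE)

  # --- song emission --------------------------------------------------------
  doy <- epoch_doy(start_time)
  smult <- season_multiplier(doy, params)
  # duty-cycle targets are modulated at half the seasonal amplitude of song
  # durations: out-of-season singers sing shorter songs more than they sing
  # proportionally less of the time
  smult_d <- 1 + (smult - 1) / 2
  dur_s <- duration_h * 3600
  songs <- list()
  t <- stats::runif(1, 0, 120)
  while (t < dur_s) {
    di <- findInterval(t / 3600, states$t0_h)
    state <- states$state[di]
    dwell_end <- states$t1_h[di] * 3600
    if (state == "fast" && silent_fast) { t <- dwell_end + 1; next }
    sp <- base_speed[di]
    dur_min <- (params$song_base_min - params$song_speed_slope * sp) *
      smult * stats::rlnorm(1, 0, params$song_sdlog)
    if (state == "fast") dur_min <- dur_min * params$fast_song_factor
    dur_min <- max(params$song_min_min, dur_min)
    s_end <- min(t + dur_min * 60, dwell_end, dur_s)
    if (s_end - t >= params$song_min_min * 60) {
      songs[[length(songs) + 1]] <- c(t, s_end)
      drange <- if (state == "slow") params$slow_duty_range else params$fast_duty_range
      d <- clamp(stats::runif(1, drange[1], drange[2]) * smult_d, 2, 95) / 100
      rrange <- if (state == "slow") params$rest_range_min else params$fast_rest_range_min
      # rests follow a truncated exponential anchored at the range minimum,
      # with mean excess set by the duty-cycle target: the realized rest
      # distribution decays smoothly over the configured range instead of
      # piling at the minimum, as a hard clamp of the duty-implied rest would
      implied <- ((s_end - t) / 60) * (1 - d) / d
      span <- rrange[2] - rrange[1]
      mean_excess <- clamp(implied - rrange[1], 0.8, span)
      rest_min <- rrange[1] + min(stats::rexp(1, 1 / mean_excess), span)
      # occasionally the silence is a travel gap — an intermediate silence
      # longer than a breathing rest but shorter than a bout break
      if (stats::runif(1) < params$travel_gap_p)
        rest_min <- params$travel_gap_min_min +
          stats::rexp(1, 1 / params$travel_gap_mean_min)
      t <- s_end + rest_min * 60
    } else {
      t <- dwell_end + 1
    }
  }
  songs <- if (length(songs) == 0)
    matrix(numeric(0), ncol = 2) else do.call(rbind, songs)

  # --- carve inter-bout gaps ------------------------------------------------
  if (n_bouts > 1 && nrow(songs) > 0) {
    centers <- (seq_len(n_bouts - 1) / n_bouts +
                  stats::runif(n_bouts - 1, -0.05, 0.05)) * dur_s
    for (gc in centers) {
      gap_min <- params$interbout_gap_min_min +
        stats::rexp(1, 1 / params$interbout_gap_mean_min)
      g0 <- gc - gap_min * 30; g1 <- gc + gap_min * 30
      keep <- songs[, 2] <= g0 | songs[, 1] >= g1
      songs <- songs[keep, , drop = FALSE]
    }
  }

  # --- realize songs as 20 Hz notes ----------------------------------------
  notes <- list()
  for (i in seq_len(nrow(songs))) {
    s0 <- songs[i, 1]; s1 <- songs[i, 2]
    ini <- stats::runif(1, params$ini_range_s[1], params$ini_range_s[2])
    starts <- seq(s0, s1 - params$note_duration_s, by = ini)
    if (length(starts) < 3) next
    jit <- stats::runif(length(starts), -0.4, 0.4)
    jit[1] <- 0
    notes[[length(notes) + 1]] <- starts + jit
  }
  note_starts <- if (length(notes)) sort(unlist(notes)) else numeric(0)
  notes_df <- data.frame(singer_id = rep(singer_id, length(note_starts)),
                         start = start_time + note_starts,
                         duration = rep(params$note_duration_s, length(note_starts)),
                         stringsAsFactors = FALSE)
  songs_df <- data.frame(singer_id = rep(singer_id, nrow(songs)),
                         start = start_time + songs[, 1],
                         end = start_time + songs[, 2],
                         stringsAsFactors = FALSE)
  path$singer_id <- singer_id
  list(path = path, notes = notes_df, songs = songs_df, states = states,
       singer_id = singer_id, start_time = start_time, duration_h = duration_h)
}

#' Decimate a movement path to track locations
#'
#' Greedy thinning along the path timeline: the first point is emitted, and
#' each subsequent point is emitted when its distance from the last emitted
#' location reaches `min_separation_km` — emulating acoustic localizations
#' spaced at least 10 km apart.
#'
#' @param path data frame with `time` and either `x_km`/`y_km` or `lat`/`lon`
#'   columns (plus optional `singer_id`).
#' @param min_separation_km minimum separation between successive emitted
#'   locations (default 10 km).
#' @return localization table (subset of path rows, original columns
#'   retained).
#' @export
decimate_locations <- function(path, min_separation_km = 10) {
  n <- nrow(path)
  if (n == 0) return(path)
  planar <- locations_planar(path)
  keep <- integer(n); keep[1] <- 1L; m <- 1L; last <- 1L
  for (i in 2:n) {
    d <- if (planar)
      sqrt((path$x_km[i] - path$x_km[last])^2 + (path$y_km[i] - path$y_km[last])^2)
    else great_circle_km(path$lat[last], path$lon[last], path$lat[i], path$lon[i])
    if (d >= min_separation_km) {
      m <- m + 1L; keep[m] <- i; last <- i
    }
  }
  out <- path[keep[seq_len(m)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert planar kilometre coordinates to latitude/longitude
#'
#' Local-tangent-plane conversion around an origin, for synthetic scenarios
#' that need geographic output.
#' @param path data frame with `x_km`, `y_km`.
#' @param origin_lat,origin_lon origin of the local plane (degrees).
#' @return the data frame with `lat`/`lon` columns added (planar columns
#'   dropped).
#' @export
planar_to_latlon <- function(path, origin_lat, origin_lon) {
  lat <- origin_lat + (path$y_km / EARTH_RADIUS_KM) * 180 / pi
  lon <- origin_lon + (path$x_km / (EARTH_RADIUS_KM * cos(origin_lat * pi / 180))) * 180 / pi
  out <- path[, setdiff(names(path), c("x_km", "y_km")), drop = FALSE]
  out$lat <- lat; out$lon <- lon
  out
}

#' Generate a synthetic singer cohort
#'
#' Draws per-singer heterogeneity (a slow-only fraction, silent-vs-fragmented
#' fast singing, track duration, number of bouts, season and year), simulates
#' each singer with [simulate_singer()], decimates the true paths to
#' locations at least `min_separation_km` apart, and adds Gaussian
#' localization noise. Start dates are seasonally weighted: 75% of tracks
#' fall in the mid-September to mid-March singing season. Deterministic given
#' `seed`.
#'
#' @param n_tracks number of singer tracks (default 163, the scale of the
#'   reference cohort).
#' @param params a [behavior_params()].
#' @param seed optional integer seed.
#' @param min_separation_km location decimation threshold (default 10).
#' @param loc_noise_km s.d. of isotropic localization noise added after
#'   decimation (default 0.3 km).
#' @param duration_meanlog,duration_sdlog,duration_range_h lognormal draw and
#'   clamp range for track durations (defaults give a median near 9 h and a
#'   1.5-70 h range).
#' @param years calendar years to sample track starts from.
#' @param geographic if `TRUE`, convert each singer's planar track to
#'   lat/lon around a random North Atlantic origin; default planar km.
#' @return list with `notes`, `locations`, `songs` (true songs), `truth`
#'   (per-singer data frame: `singer_id`, `slow_only`, `silent_fast`,
#'   `n_bouts`, `duration_h`, `year`, `day_of_year`, `start_time`), `params`
#'   and `seed`.
#' @export
generate_cohort <- function(n_tracks = 163, params = behavior_params(),
                            seed = NULL, min_separation_km = 10,
                            loc_noise_km = 0.3,
                            duration_meanlog = log(9.3),
                            duration_sdlog = 0.85,
                            duration_range_h = c(1.5, 70),
                            years = 2003:2009,
                            geographic = FALSE) {
  stopifnot(inherits(params, "behavior_params"), n_tracks >= 1)
  if (!is.null(seed)) set.seed(seed)
  notes <- vector("list", n_tracks)
  locs <- vector("list", n_tracks)
  songs <- vector("list", n_tracks)
  truth <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    id <- sprintf("Fin-%03d", i)
    slow_only <- stats::runif(1) < params$p_slow_only
    silent_fast <- stats::runif(1) < params$p_silent_fast
    n_bouts <- sample(1:3, 1, prob = c(0.57, 0.30, 0.13))
    # slow-only singers station-keep and sing long bouts; their tracks are
    # drawn longer (and floored higher) so slow movers still accumulate the
    # three 10-km-spaced locations the inclusion filter demands
    duration_h <- if (slow_only)
      clamp(stats::rlnorm(1, duration_meanlog + 0.55, 0.6),
            max(duration_range_h[1], 4), duration_range_h[2])
    else
      clamp(stats::rlnorm(1, duration_meanlog - 0.15, duration_sdlog),
            duration_range_h[1], duration_range_h[2])
    year <- sample(years, 1)
    # 75% of tracks in the mid-September..mid-March singing season
    doy <- if (stats::runif(1) < 0.75) {
      d <- sample.int(182, 1) + 257   # 258..439 wraps past year end
      if (d > 365) d - 365 else d
    } else sample(75:257, 1)
    start_time <- as.numeric(ISOdatetime(year, 1, 1, 0, 0, 0, tz = "UTC")) +
      (doy - 1) * 86400 + stats::runif(1, 0, 86400)
    sim <- simulate_singer(params, duration_h, seed = NULL, singer_id = id,
                           start_time = start_time, slow_only = slow_only,
                           silent_fast = silent_fast, n_bouts = n_bouts)
    loc <- decimate_locations(sim$path, min_separation_km)
    loc <- loc[, c("singer_id", "time", "x_km", "y_km")]
    if (loc_noise_km > 0) {
      loc$x_km <- loc$x_km + stats::rnorm(nrow(loc), 0, loc_noise_km)
      loc$y_km <- loc$y_km + stats::rnorm(nrow(loc), 0, loc_noise_km)
    }
    if (geographic) {
      origin <- c(stats::runif(1, 35, 55), stats::runif(1, -45, -15))
      loc <- planar_to_latlon(loc, origin[1], origin[2])
      loc <- loc[, c("singer_id", "time", "lat", "lon")]
    }
    notes[[i]] <- sim$notes
    locs[[i]] <- loc
    songs[[i]] <- sim$songs
    truth[[i]] <- data.frame(singer_id = id, slow_only = slow_only,
                             silent_fast = silent_fast, n_bouts = n_bouts,
                             duration_h = duration_h, year = year,
                             day_of_year = doy, start_time = start_time,
                             stringsAsFactors = FALSE)
  }
  list(notes = do.call(rbind, notes), locations = do.call(rbind, locs),
       songs = do.call(rbind, songs), truth = do.call(rbind, truth),
       params = params, seed = seed)
}
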