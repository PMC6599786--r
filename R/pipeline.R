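# End-to-end analysis: notes + locations -> songs -> BEC/bouts -> tracks ->
# cohort statistics and additive models, plus the markdown report.

#' Run the full singing/swimming analysis
#'
#' Assembles songs, estimates the bout-ending criterion from the pooled
#' inter-song-interval distribution (falling back to `cfg$default_bec` when
#' the biexponential cannot be fit, e.g. too few intervals), segments bouts,
#' builds and filters tracks, and computes the cohort statistics: per-track
#' summaries, the speed x duty-cycle histogram with its bimodality summary,
#' regime transition patterns, the matched-pairs singing/non-singing speed
#' test (singers with at least two bouts), and the additive smooth models for
#' duty-cycle and song duration (fitted when at least 40 tracks survive the
#' filter).
#'
#' @param notes note-event table (see [read_notes()]).
#' @param locations localization table (see [read_locations()]).
#' @param cfg an [analysis_config()].
#' @return object of class `finsong_analysis`; see the fields in the source
#'   or `print()` it for the headline numbers.
#' @export
run_pipeline <- function(notes, locations, cfg = analysis_config()) {
  songs <- assemble_songs(notes, cfg)
  isi <- inter_song_intervals(songs)
  bout_fit <- tryCatch(
    fit_biexponential(interval_log_frequency(isi, cfg$bin_width)),
    error = function(e) {
      message("BEC estimation unavailable (", conditionMessage(e),
              "); using default BEC of ", cfg$default_bec, " min")
      NULL
    })
  bec <- if (!is.null(bout_fit) && is.finite(bout_fit$bec)) bout_fit$bec
         else cfg$default_bec

  tracks_all <- build_tracks(notes, locations, cfg, bec = bec, songs = songs)
  filt <- filter_tracks(tracks_all, cfg)
  tracks <- filt$tracks
  if (length(tracks) == 0) stop("no tracks pass the inclusion filter", call. = FALSE)

  tt <- track_table(tracks)
  segments <- segment_table(tracks)
  cohort <- cohort_summary(tt)
  histogram <- speed_duty_histogram(segments, cfg$speed_bin, cfg$duty_bin)
  transitions <- transition_summary(tt)

  pairs <- singing_speed_pairs(tracks)
  paired <- if (nrow(pairs) >= 2)
    paired_speed_test(pairs$singing_kmh, pairs$nonsinging_kmh) else NULL

  mt <- model_table(tt)
  models <- list()
  if (nrow(mt) >= 40) {
    models$duty_cycle <- tryCatch(
      fit_additive_model(mt, "duty_cycle", cfg), error = function(e) NULL)
    models$song_duration <- tryCatch(
      fit_additive_model(mt, "song_duration", cfg), error = function(e) NULL)
  }

  structure(list(cfg = cfg, songs = songs, intervals_min = isi,
                 bout_fit = bout_fit, bec = bec, tracks = tracks,
                 exclusions = filt$exclusions, track_table = tt,
                 segments = segments, cohort = cohort,
                 histogram = histogram, transitions = transitions,
                 speed_pairs = pairs, paired_test = paired,
                 model_table = mt, models = models),
            class = "finsong_analysis")
}

#' Regime transition summary
#'
#' Start-regime counts and the distribution of transition patterns, overall
#' and conditional on the starting regime.
#' @param tt a [track_table()].
#' @return list with `n_tracks`, `started_slow`, `started_slow_pct`,
#'   `pattern_counts` (table), `by_start` (pattern proportions within each
#'   start regime) and `slow_only_fraction` (tracks whose segments never
#'   reach the fast regime).
#' @export
transition_summary <- function(tt) {
  ok <- !is.na(tt$start_regime)
  d <- tt[ok, , drop = FALSE]
  started_slow <- sum(d$start_regime == "slow")
  by_start <- lapply(split(d$transition, d$start_regime),
                     function(x) prop.table(table(x)))
  slow_only <- mean(d$transition %in% c("stayed_slow") |
                      (d$start_regime == "slow" & d$transition == "undefined"))
  list(n_tracks = nrow(d), started_slow = started_slow,
       started_slow_pct = 100 * started_slow / max(nrow(d), 1),
       pattern_counts = table(d$transition), by_start = by_start,
       slow_only_fraction = slow_only)
}

#' @export
print.finsong_analysis <- function(x, ...) {
  cat("Fin whale singing/swimming analysis\n")
  cat(sprintf("  %d tracks (%d excluded), %d segments, %d songs, BEC %g min\n",
              length(x$tracks), nrow(x$exclusions), nrow(x$segments),
              nrow(x$songs), x$bec))
  sp <- x$cohort[x$cohort$variable == "speed_kmh", ]
  dc <- x$cohort[x$cohort$variable == "duty_cycle_pct", ]
  cat(sprintf("  mean track speed %.1f km/h, mean duty-cycle %.1f%%\n",
              sp$mean, dc$mean))
  cat(sprintf("  duty-cycle modes: %.0f%% high (75-90%%), %.0f%% low (0-5%%)\n",
              100 * x$histogram$high_mode_fraction,
              100 * x$histogram$low_mode_fraction))
  if (!is.null(x$paired_test))
    cat(sprintf("  paired singing/non-singing speed test: t_%d = %.3g, p = %.3g\n",
                x$paired_test$degrees_of_freedom, x$paired_test$t_statistic,
                x$paired_test$p_value))
  for (m in x$models)
    if (!is.null(m))
      cat(sprintf("  %s model: adj r2 = %.2f, retained: %s\n", m$response,
                  m$adj_r2, paste(m$terms$variable, collapse = ", ")))
  invisible(x)
}

fmt <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

#' Render the analysis report
#'
#' A human-readable markdown summary of an analysis: cohort descriptive
#' statistics (per-track means), regime and transition percentages, the
#' speed x duty-cycle bimodality summary, the matched-pairs speed test, the
#' bout-ending criterion and the additive model tables. Deterministic for a
#' fixed analysis object.
#'
#' @param analysis a `finsong_analysis` from [run_pipeline()].
#' @param file optional path to write the report to.
#' @return character vector of markdown lines, invisibly if `file` is given.
#' @export
render_report <- function(analysis, file = NULL) {
  x <- analysis
  if (length(x$tracks) == 0) stop("empty analysis: nothing to report", call. = FALSE)
  L <- c("# Singing and swimming report", "",
         sprintf("Tracks analysed: %d (excluded: %d). Segments: %d. Songs: %d.",
                 length(x$tracks), nrow(x$exclusions), nrow(x$segments),
                 nrow(x$songs)),
         sprintf("Inter-song-intervals: n = %d. Bout-ending criterion: %g min%s.",
                 length(x$intervals_min), x$bec,
                 if (is.null(x$bout_fit)) " (default; no biexponential fit)"
                 else sprintf(" (biexponential crossing %.2f min)",
                              x$bout_fit$bec_exact)),
         "", "## Cohort statistics (per-track means)", "",
         "| variable | mean | s.e.m. | s.d. | median | min | max |",
         "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(x$cohort))) {
    r <- x$cohort[i, ]
    L <- c(L, sprintf("| %s | %s | %s | %s | %s | %s | %s |", r$variable,
                      fmt(r$mean), fmt(r$sem), fmt(r$sd), fmt(r$median),
                      fmt(r$min), fmt(r$max)))
  }
  tr <- x$transitions
  L <- c(L, "", "## Regimes and transitions", "",
         sprintf("- started slow: %d/%d (%.0f%%)", tr$started_slow,
                 tr$n_tracks, tr$started_slow_pct),
         sprintf("- never exceeded the fast threshold: %.0f%% of tracks",
                 100 * tr$slow_only_fraction),
         sprintf("- patterns: %s",
                 paste(sprintf("%s %d", names(tr$pattern_counts),
                               as.integer(tr$pattern_counts)), collapse = ", ")),
         "", "## Speed x duty-cycle distribution", "",
         sprintf("- high duty-cycle mode (75-90%%): %.1f%% of %d segments",
                 100 * x$histogram$high_mode_fraction, x$histogram$n),
         sprintf("- low duty-cycle mode (0-5%%): %.1f%% of %d segments",
                 100 * x$histogram$low_mode_fraction, x$histogram$n))
  if (!is.null(x$paired_test)) {
    p <- x$paired_test
    L <- c(L, "", "## Singing vs non-singing swimming speed", "",
           sprintf("Matched-pairs t-test over %d singers with multiple bouts: t_%d = %.3g, p = %.4g.",
                   p$n_pairs, p$degrees_of_freedom, p$t_statistic, p$p_value))
  }
  for (m in x$models) {
    if (is.null(m)) next
    L <- c(L, "", sprintf("## Additive model: %s", m$response), "",
           sprintf("Adjusted r-squared: %.2f. n = %d tracks.%s", m$adj_r2, m$n,
                   if (length(m$eliminated))
                     sprintf(" Eliminated: %s.", paste(m$eliminated, collapse = ", "))
                   else ""),
           "", "| variable | d.f. | F | p |", "|---|---|---|---|")
    for (i in seq_len(nrow(m$terms)))
      L <- c(L, sprintf("| %s | %.1f | %.2f | %.3g |", m$terms$variable[i],
                        m$terms$edf[i], m$terms$F[i], m$terms$p_value[i]))
  }
  if (!is.null(file)) {
    writeLines(L, file)
    return(invisible(L))
  }
  L
}
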