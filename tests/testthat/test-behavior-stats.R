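test_that("cohort summary is computed over per-track means", {
  tt <- data.frame(singer_id = c("A", "B"),
                   n_locations = c(4, 5), track_length_km = c(30, 50),
                   track_duration_h = c(5, 8), total_singing_duration_h = c(5, 8),
                   mean_speed_kmh = c(4, 6), min_speed_kmh = c(2, 3),
                   max_speed_kmh = c(6, 9),
                   mean_duty_cycle_pct = c(80, 40), min_duty_cycle_pct = c(60, 10),
                   max_duty_cycle_pct = c(95, 70),
                   mean_song_duration_min = c(12, 8),
                   min_song_duration_min = c(6, 3), max_song_duration_min = c(20, 12))
  cs <- cohort_summary(tt)
  sp <- cs[cs$variable == "speed_kmh", ]
  expect_equal(sp$mean, 5)       # mean of track means: (4 + 6) / 2
  expect_equal(sp$sem, 1)        # sd(c(4, 6)) / sqrt(2)
  expect_equal(sp$mean_of_min, 2.5)
  expect_equal(sp$mean_of_max, 7.5)
  expect_equal(cs[cs$variable == "track_length_km", "median"], 40)

  # single-track cohort: mean defined, s.e.m. flagged undefined
  one <- cohort_summary(tt[1, ])
  expect_true(attr(one, "sem_undefined"))
  expect_true(is.na(one$sem[1]))
  expect_equal(one[one$variable == "speed_kmh", "mean"], 4)

  expect_error(cohort_summary(tt[0, ]), "empty cohort")
})

test_that("cohort summary equals an independent recomputation on simulated tracks", {
  coh <- tiny_cohort(6)
  tracks <- build_tracks(coh$notes, coh$locations, analysis_config(planar = TRUE))
  cs <- cohort_summary(tracks)
  # direct recomputation from the raw track objects
  means <- vapply(tracks, function(tr) mean(tr$segments$speed_kmh), 0)
  expect_equal(cs[cs$variable == "speed_kmh", "mean"], mean(means))
  expect_equal(cs[cs$variable == "speed_kmh", "sem"],
               sd(means) / sqrt(length(means)))
  expect_equal(cs[cs$variable == "track_length_km", "mean"],
               mean(vapply(tracks, function(tr) sum(tr$segments$distance_km), 0)))
  # pooling segments would give a different number than the track-level mean
  pooled <- mean(segment_table(tracks)$speed_kmh)
  expect_false(isTRUE(all.equal(pooled, cs[cs$variable == "speed_kmh", "mean"])))
})

test_that("speed-duty histogram counts every segment once and flags modes", {
  segs <- data.frame(speed_kmh = c(0.5), duty_cycle_pct = c(80))
  h <- speed_duty_histogram(segs)
  expect_equal(sum(h$counts), 1)
  expect_equal(max(h$log10_counts, na.rm = TRUE), 0)  # single cell, log10(1)

  set.seed(6)
  segs2 <- data.frame(speed_kmh = runif(500, 0, 20),
                      duty_cycle_pct = runif(500, 0, 100))
  h2 <- speed_duty_histogram(segs2)
  expect_equal(sum(h2$counts), 500)
  expect_true(all(is.na(h2$log10_counts[h2$counts == 0])))
  # permutation invariance
  h3 <- speed_duty_histogram(segs2[sample(500), ])
  expect_equal(h2$counts, h3$counts)
  expect_equal(h2$high_mode_fraction, mean(segs2$duty_cycle_pct >= 75 &
                                             segs2$duty_cycle_pct <= 90))
  expect_equal(h2$low_mode_fraction, mean(segs2$duty_cycle_pct <= 5))
  # duty-cycles of exactly 100 are binned
  expect_equal(sum(speed_duty_histogram(
    data.frame(speed_kmh = 3, duty_cycle_pct = 100))$counts), 1)
})

test_that("paired test matches the textbook formula and one-sample identity", {
  set.seed(12)
  x <- runif(10, 3, 9); y <- runif(10, 3, 9)
  got <- paired_speed_test(x, y)
  d <- x - y
  t_formula <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_lt(abs(got$t_statistic - t_formula), 1e-10)
  one_sample <- t.test(d)
  expect_lt(abs(got$t_statistic - unname(one_sample$statistic)), 1e-10)
  expect_lt(abs(got$p_value - one_sample$p.value), 1e-10)
  expect_equal(got$degrees_of_freedom, 9)

  same <- paired_speed_test(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  degen <- paired_speed_test(c(1, 2, 3), c(2, 3, 4))
  expect_true(degen$degenerate)
  expect_equal(degen$mean_difference, -1)

  expect_error(paired_speed_test(1, 2), "at least 2")
})

test_that("Johnson SL normalizes lognormal samples", {
  passes <- 0
  for (s in 1:100) {
    set.seed(3000 + s)
    x <- rlnorm(200, meanlog = 1.2, sdlog = 0.6)
    fit <- fit_johnson_sl(x)
    if (stats::shapiro.test(fit$transformed)$p.value > 0.01) passes <- passes + 1
  }
  expect_gte(passes, 95)
})

test_that("Johnson SL reduces skewness and does no serious harm when not needed", {
  set.seed(17)
  x <- rlnorm(500, 0, 0.8)
  fit <- fit_johnson_sl(x)
  expect_lt(abs(finsong:::sample_skewness(fit$transformed)),
            abs(finsong:::sample_skewness(x)))
  expect_gt(fit$delta, 0)
  expect_lt(fit$xi, min(x))
  # transform and inverse are mutual inverses
  expect_equal(johnson_inverse(fit, fit$transformed), x, tolerance = 1e-9)

  # near-normal positive input: transformed skewness stays small
  y <- rnorm(500, 50, 5)
  fit2 <- fit_johnson_sl(y)
  expect_lt(abs(finsong:::sample_skewness(fit2$transformed)),
            abs(finsong:::sample_skewness(y)) + 0.5)

  expect_error(fit_johnson_sl(rep(3, 50)), "constant")
  expect_error(fit_johnson_sl(rlnorm(10)), "at least 20")
})
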