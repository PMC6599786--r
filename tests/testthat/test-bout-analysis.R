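test_that("interval log-frequency bins and drops empties", {
  lf <- interval_log_frequency(rep(5.5, 100), 1)
  expect_equal(lf$t, 5.5)
  expect_equal(lf$log10_count, 2)

  lf2 <- interval_log_frequency(c(rep(1.5, 10), 9.5), 1)
  expect_equal(lf2$log10_count, c(1, 0))
  expect_equal(length(lf2$t), 2)  # empty bins between are gone

  expect_error(interval_log_frequency(numeric(0)), "no intervals")
  expect_error(interval_log_frequency(c(1, -2)), "positive")
  expect_error(interval_log_frequency(5, bin_width = 0), "bin_width")
})

test_that("exponential intervals give the closed-form log10 slope", {
  set.seed(3)
  x <- rexp(1e4, 0.2)
  lf <- interval_log_frequency(x, 1)
  # fit the decaying range where expected counts are well populated
  keep <- lf$count >= 5
  fit <- lm(lf$log10_count[keep] ~ lf$t[keep])
  ci <- confint(fit)[2, ]
  expect_true(ci[1] <= -0.2 / log(10) && -0.2 / log(10) <= ci[2])
})

test_that("noiseless biexponential parameters are recovered to 1%", {
  t <- seq(0.5, 150.5, by = 1)
  y <- 800 * exp(-0.2 * t) + 20 * exp(-0.01 * t)
  fit <- fit_biexponential(t, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$a_f - 800) / 800, 0.01)
  expect_lt(abs(fit$lambda_f - 0.2) / 0.2, 0.01)
  expect_lt(abs(fit$a_s - 20) / 20, 0.01)
  expect_lt(abs(fit$lambda_s - 0.01) / 0.01, 0.01)
})

test_that("single-exponential data are rejected as not biexponential", {
  set.seed(5)
  x <- rexp(5000, 0.15)
  lf <- interval_log_frequency(x, 1)
  expect_error(fit_biexponential(lf), "biexponential")
  expect_error(fit_biexponential(1:4, c(10, 5, 3, 2)), "5 non-empty bins")
})

test_that("two-exponential mixtures are recovered within tolerance", {
  # median over seeds: rates within 20% of truth
  rate_f <- 1 / 5; rate_s <- 1 / 100
  err_f <- err_s <- numeric(11)
  for (s in 1:11) {
    set.seed(100 + s)
    n <- 1e4
    fast <- rbinom(1, n, 0.8)
    x <- c(rexp(fast, rate_f), rexp(n - fast, rate_s))
    fit <- fit_biexponential(interval_log_frequency(x, 1))
    err_f[s] <- abs(fit$lambda_f - rate_f) / rate_f
    err_s[s] <- abs(fit$lambda_s - rate_s) / rate_s
  }
  expect_lt(median(err_f), 0.2)
  expect_lt(median(err_s), 0.2)
})

test_that("BEC closed form matches hand arithmetic and errors on degenerate fits", {
  fit <- structure(list(a_f = 800, lambda_f = 0.2, a_s = 20, lambda_s = 0.01),
                   class = "bout_model_fit")
  expect_equal(bec_from_fit(fit), log(40) / 0.19, tolerance = 1e-12)
  expect_equal(bec_from_fit(fit, operational = TRUE), 19)
  # the density reading shifts the crossing by ln(ratio of rates)/(dlambda)
  expect_equal(bec_from_fit(fit, method = "density"),
               log(40 * 0.2 / 0.01) / 0.19, tolerance = 1e-12)

  degen <- structure(list(a_f = 20, lambda_f = 0.2, a_s = 20, lambda_s = 0.01),
                     class = "bout_model_fit")
  expect_error(bec_from_fit(degen), "do not cross")
  swapped <- structure(list(a_f = 800, lambda_f = 0.01, a_s = 20, lambda_s = 0.2),
                       class = "bout_model_fit")
  expect_error(bec_from_fit(swapped), "lambda_f > lambda_s")
})

test_that("bout segmentation splits at intervals >= the BEC", {
  # songs with inter-song-intervals 4, 36, 5 minutes
  songs <- make_songs(c(0, 14, 60, 75), c(10, 24, 70, 85))
  bouts <- segment_bouts(songs, bec = 35)
  expect_equal(nrow(bouts), 2)
  expect_equal(bouts$n_songs, c(2, 2))
  expect_equal(inter_bout_intervals(bouts), 36)

  # all intervals below the BEC: a single bout; no inter-bout-intervals
  one <- segment_bouts(songs, bec = 40)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_songs, 4)
  expect_equal(inter_bout_intervals(one), numeric(0))

  # an interval of exactly the BEC splits ("greater than or equal to")
  exact <- make_songs(c(0, 45), c(10, 55))
  expect_equal(nrow(segment_bouts(exact, bec = 35)), 2)
  expect_equal(nrow(segment_bouts(exact, bec = 35.0001)), 1)
})

test_that("bout counts follow the interval threshold identity", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    gaps <- c(runif(n - 1, 1, 60))
    durs <- runif(n, 2, 12)
    starts <- cumsum(c(0, durs[-n] + gaps))
    songs <- make_songs(starts, starts + durs)
    for (bec in c(5, 20, 35, 50)) {
      bouts <- segment_bouts(songs, bec)
      expect_equal(nrow(bouts), 1 + sum(gaps >= bec))
      expect_equal(sum(bouts$n_songs), n)
      ibi <- inter_bout_intervals(bouts)
      if (length(ibi) > 0) expect_true(all(ibi >= bec))
    }
    # monotonicity: a larger BEC never yields more bouts
    counts <- vapply(c(5, 20, 35, 50),
                     function(b) nrow(segment_bouts(songs, b)), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("simulated multi-bout singers show gaps at least the configured minimum", {
  p <- behavior_params()
  sim <- simulate_singer(p, duration_h = 30, seed = 21, slow_only = TRUE,
                         n_bouts = 3,
                         start_time = as.numeric(ISOdatetime(2006, 1, 10, 0, 0, 0, tz = "UTC")))
  songs <- assemble_songs(sim$notes)
  bouts <- segment_bouts(songs, bec = 35)
  expect_gte(nrow(bouts), 2)
  ibi <- inter_bout_intervals(bouts)
  expect_true(all(ibi >= p$interbout_gap_min_min))
})

test_that("BEC diagnostics report both readings across bin widths", {
  set.seed(13)
  x <- c(rexp(6000, 1 / 5), rexp(1500, 1 / 80))
  d <- bec_diagnostics(x, bin_widths = c(1, 2))
  expect_equal(nrow(d), 2)
  expect_true(all(is.finite(d$bec_crossing)))
  # density reading always sits above the count-crossing reading
  expect_true(all(d$bec_density > d$bec_crossing))
})

test_that("the diagnostic plot writes a file", {
  set.seed(2)
  x <- c(rexp(5000, 1 / 5), rexp(1000, 1 / 90))
  lf <- interval_log_frequency(x, 1)
  fit <- fit_biexponential(lf)
  f <- withr::local_tempfile(fileext = ".png")
  plot_bec_fit(fit, lf, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
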