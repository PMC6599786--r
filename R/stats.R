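# Cohort statistics: track-level descriptive statistics, the bimodal
# speed x duty-cycle histogram, the matched-pairs singing/non-singing speed
# comparison, the Johnson SL normalizing transform, and the additive smooth
# models of singing against speed and season.

#' Cohort descriptive statistics
#'
#' Tracks are the unit of analysis — each whale is represented once — so all
#' cohort statistics are computed over per-track values, never over pooled
#' segments. For segment-derived variables (speed, duty-cycle, song duration)
#' the per-track value is the track mean, and the cohort report additionally
#' carries the mean of per-track minima and maxima.
#'
#' @param tracks list of `singer_track` objects, or a [track_table()] data
#'   frame.
#' @return data frame of class `cohort_summary`, one row per variable with
#'   columns `variable`, `n_tracks`, `mean` (mean of track means), `sem`
#'   (standard error of that mean; `NA` with a flag for a single track), `sd`,
#'   `median`, `min`, `max` (over track means) and, for segment-derived
#'   variables, `mean_of_min` and `mean_of_max`.
#' @export
cohort_summary <- function(tracks) {
  tt <- if (is.data.frame(tracks)) tracks else track_table(tracks)
  if (nrow(tt) == 0) stop("empty cohort: no tracks to summarize", call. = FALSE)
  n <- nrow(tt)
  row_for <- function(variable, values, mins = NULL, maxs = NULL) {
    v <- values[is.finite(values)]
    data.frame(variable = variable, n_tracks = length(v),
               mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = stats::median(v), min = min(v), max = max(v),
               mean_of_min = if (is.null(mins)) NA_real_ else mean(mins, na.rm = TRUE),
               mean_of_max = if (is.null(maxs)) NA_real_ else mean(maxs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_for("track_length_km", tt$track_length_km),
    row_for("track_duration_h", tt$track_duration_h),
    row_for("total_singing_duration_h", tt$total_singing_duration_h),
    row_for("n_locations", tt$n_locations),
    row_for("speed_kmh", tt$mean_speed_kmh, tt$min_speed_kmh, tt$max_speed_kmh),
    row_for("duty_cycle_pct", tt$mean_duty_cycle_pct,
            tt$min_duty_cycle_pct, tt$max_duty_cycle_pct),
    row_for("song_duration_min", tt$mean_song_duration_min,
            tt$min_song_duration_min, tt$max_song_duration_min))
  attr(out, "n_tracks") <- n
  attr(out, "sem_undefined") <- n < 2
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Two-dimensional speed x duty-cycle histogram
#'
#' Counts track segments on a speed-by-duty-cycle grid and reports the counts
#' on a log10 scale (cells with zero count are left `NA`: there is no log of
#' zero). Also reports the bimodality summary used to characterize the two
#' swimming/singing modes: the fraction of segments in the high duty-cycle
#' band (75-90%) and in the low band (0-5%).
#'
#' @param segments segment table (see [segment_table()]) with `speed_kmh` and
#'   `duty_cycle_pct` columns.
#' @param speed_bin speed bin width in km/h (default 1).
#' @param duty_bin duty-cycle bin width in percentage points (default 5).
#' @return object of class `speed_duty_histogram`: list with `counts` and
#'   `log10_counts` matrices (speed bins x duty bins), `speed_breaks`,
#'   `duty_breaks`, `n`, `high_mode_fraction`, `low_mode_fraction`.
#' @export
speed_duty_histogram <- function(segments, speed_bin = 1, duty_bin = 5) {
  stopifnot(speed_bin > 0, duty_bin > 0)
  v <- segments$speed_kmh
  d <- segments$duty_cycle_pct
  if (length(v) == 0) stop("no segments to histogram", call. = FALSE)
  sb <- seq(0, max(ceiling(max(v) / speed_bin), 1) * speed_bin, by = speed_bin)
  if (max(v) >= max(sb)) sb <- c(sb, max(sb) + speed_bin)
  db <- seq(0, 100, by = duty_bin)
  if (max(db) < 100) db <- c(db, 100)
  si <- cut(v, sb, right = FALSE, include.lowest = TRUE)
  di <- cut(d, db, right = FALSE, include.lowest = TRUE)
  # top duty bin must include 100% exactly
  di[d >= 100 - 1e-9] <- levels(di)[length(levels(di))]
  counts <- table(si, di)
  lg <- log10(counts)
  lg[counts == 0] <- NA
  structure(list(counts = unclass(counts), log10_counts = unclass(lg),
                 speed_breaks = sb, duty_breaks = db, n = length(v),
                 high_mode_fraction = mean(d >= 75 & d <= 90),
                 low_mode_fraction = mean(d >= 0 & d <= 5)),
            class = "speed_duty_histogram")
}

#' @export
print.speed_duty_histogram <- function(x, ...) {
  cat(sprintf("Speed x duty-cycle histogram: %d segments, %d x %d cells\n",
              x$n, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  high duty-cycle mode (75-90%%): %.1f%% of segments\n",
              100 * x$high_mode_fraction))
  cat(sprintf("  low duty-cycle mode (0-5%%):   %.1f%% of segments\n",
              100 * x$low_mode_fraction))
  invisible(x)
}

#' Matched-pairs comparison of singing and non-singing swimming speeds
#'
#' Classic paired t-test on per-singer (singing, non-singing) mean speed
#' pairs, available for singers observed across at least one inter-bout
#' interval. Identical pairs give t = 0, p = 1; constant non-zero differences
#' have zero variance and are flagged degenerate rather than tested.
#'
#' @param singing per-singer mean swimming speed while singing (km/h).
#' @param nonsinging per-singer mean swimming speed while not singing, same
#'   order.
#' @return object of class `paired_test_result`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `n_pairs`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_speed_test <- function(singing, nonsinging) {
  ok <- is.finite(singing) & is.finite(nonsinging)
  singing <- singing[ok]; nonsinging <- nonsinging[ok]
  n <- length(singing)
  if (n != length(nonsinging)) stop("paired vectors differ in length", call. = FALSE)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- singing - nonsinging
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      res <- list(t_statistic = 0, degrees_of_freedom = n - 1, p_value = 1,
                  n_pairs = n, mean_difference = 0, degenerate = TRUE)
    } else {
      res <- list(t_statistic = sign(mean(d)) * Inf,
                  degrees_of_freedom = n - 1, p_value = 0,
                  n_pairs = n, mean_difference = mean(d), degenerate = TRUE)
    }
    return(structure(res, class = "paired_test_result"))
  }
  tt <- stats::t.test(singing, nonsinging, paired = TRUE)
  structure(list(t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value, n_pairs = n,
                 mean_difference = mean(d), degenerate = FALSE),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Matched-pairs t-test: t_%d = %.4g, p = %.4g (n = %d pairs%s)\n",
              x$degrees_of_freedom, x$t_statistic, x$p_value, x$n_pairs,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Per-singer singing vs non-singing mean speeds
#'
#' For singers with at least two bouts, computes the overlap-weighted mean
#' segment speed during bout spans (singing) and during inter-bout spans
#' (non-singing) — the input pairs of [paired_speed_test()].
#'
#' @param tracks list of `singer_track` objects.
#' @return data frame `singer_id`, `singing_kmh`, `nonsinging_kmh` (only
#'   singers with usable overlap in both conditions).
#' @export
singing_speed_pairs <- function(tracks) {
  rows <- lapply(tracks, function(tr) {
    b <- tr$bouts
    segs <- tr$segments
    if (is.null(b) || nrow(b) < 2 || is.null(segs) || nrow(segs) == 0) return(NULL)
    b <- b[order(b$start), , drop = FALSE]
    gaps <- cbind(b$end[-nrow(b)], b$start[-1])
    w_speed <- function(spans) {
      ov <- rep(0, nrow(segs))
      for (k in seq_len(nrow(spans)))
        ov <- ov + pmax(0, pmin(segs$t_end, spans[k, 2]) - pmax(segs$t_start, spans[k, 1]))
      if (sum(ov) <= 0) return(NA_real_)
      sum(segs$speed_kmh * ov) / sum(ov)
    }
    s1 <- w_speed(cbind(b$start, b$end))
    s0 <- w_speed(gaps)
    if (!is.finite(s1) || !is.finite(s0)) return(NULL)
    data.frame(singer_id = tr$singer_id, singing_kmh = s1, nonsinging_kmh = s0,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(singer_id = character(), singing_kmh = numeric(),
                      nonsinging_kmh = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Johnson SL (lognormal) normalizing transform
#'
#' Fits the lognormal member of the Johnson system,
#' `z = gamma + delta * ln((x - xi) / lambda)` (with `lambda = 1`, the SL
#' family's scale being absorbed into `gamma`), by the percentile method:
#' sample percentiles at the normal quantiles `+/-z` and `+/-3z` with
#' `z = 0.524` determine the location `xi` and the slope pair
#' (`gamma`, `delta`). For duration- and speed-like variables the location is
#' floored at zero: alongside the percentile estimate of `xi`, a pinned
#' candidate (`xi = 0`) is always evaluated, and the location whose log
#' residuals are least skewed wins — the slope pair is affine and cannot
#' affect normality, so the location carries the whole transform. When the
#' pinned location is chosen (or the percentile discriminant shows no right
#' skew), (`gamma`, `delta`) are fit by quantile matching on `ln(x - xi)`.
#'
#' @param values positive, right-skewed sample (n >= 20).
#' @param z normal quantile anchor of the percentile method (default 0.524).
#' @param floor_xi floor the location parameter at zero (default `TRUE`).
#' @return object of class `johnson_sl_fit`: list with `xi`, `lambda`,
#'   `gamma`, `delta`, `method` (`"percentile"` or `"pinned"`) and
#'   `transformed` (the transformed sample).
#' @export
fit_johnson_sl <- function(values, z = 0.524, floor_xi = TRUE) {
  x <- values[is.finite(values)]
  if (length(x) < 20) stop("need at least 20 values", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant vector cannot be transformed", call. = FALSE)
  probs <- stats::pnorm(c(-3 * z, -z, z, 3 * z))
  q <- stats::quantile(x, probs, names = FALSE, type = 7)
  m <- q[4] - q[3]           # upper spread
  p <- q[3] - q[2]           # central spread
  xi_cand <- c(pinned = if (floor_xi && min(x) > 0) 0
                        else min(x) - 0.1 * (max(x) - min(x)) - 1e-9)
  gamma_delta <- NULL
  if (p > 0 && m / p > 1 + 1e-6) {
    ratio <- m / p
    xi_p <- (q[3] + q[2]) / 2 - (p / 2) * (ratio + 1) / (ratio - 1)
    if (xi_p < min(x) && !(floor_xi && xi_p < 0)) {
      xi_cand <- c(xi_cand, percentile = xi_p)
      gamma_delta <- c(gamma = unname(2 * z / log(ratio) *
                                        log((ratio - 1) / (p * sqrt(ratio)))),
                       delta = unname(2 * z / log(ratio)))
    }
  }
  # pick the location whose log residual scale is least skewed; the slope
  # pair (gamma, delta) is affine and does not affect normality, so location
  # quality is the whole game
  skews <- vapply(xi_cand, function(xi0)
    abs(sample_skewness(log(x - xi0))), 0)
  method <- names(which.min(skews))
  xi <- unname(xi_cand[[method]])
  if (method == "percentile") {
    gamma <- gamma_delta[["gamma"]]
    delta <- gamma_delta[["delta"]]
  } else {
    y <- log(x - xi)
    spread <- stats::quantile(y, 0.7, names = FALSE) - stats::quantile(y, 0.3, names = FALSE)
    if (spread <= 0) stop("degenerate quantile spread in Johnson fit", call. = FALSE)
    delta <- (stats::qnorm(0.7) - stats::qnorm(0.3)) / spread
    gamma <- -delta * stats::median(y)
  }
  if (any(x <= xi)) stop("location fit leaves values <= xi", call. = FALSE)
  if (!is.finite(delta) || delta <= 0)
    stop("Johnson SL fit failed: non-positive shape", call. = FALSE)
  fit <- structure(list(xi = unname(xi), lambda = 1, gamma = unname(gamma),
                        delta = unname(delta), method = method),
                   class = "johnson_sl_fit")
  fit$transformed <- johnson_transform(fit, values)
  fit
}

#' Apply / invert a Johnson SL transform
#' @param fit a `johnson_sl_fit`.
#' @param x values on the original scale (for `johnson_transform`) or the
#'   normal scale (for `johnson_inverse`).
#' @return transformed values.
#' @export
johnson_transform <- function(fit, x) {
  fit$gamma + fit$delta * log((x - fit$xi) / fit$lambda)
}

#' @rdname johnson_transform
#' @export
johnson_inverse <- function(fit, x) {
  fit$xi + fit$lambda * exp((x - fit$gamma) / fit$delta)
}
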