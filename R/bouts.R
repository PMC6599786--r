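# Bout analysis: estimate the bout-ending criterion (BEC) from the
# inter-song-interval distribution and split song sequences into bouts.
#
# The interval distribution mixes two processes: short within-bout rests
# (breathing pauses between songs) and long between-bout gaps. Following the
# log-survivorship tradition of bout analysis, a four-parameter biexponential
#   y(t) = a_f * exp(-lambda_f * t) + a_s * exp(-lambda_s * t)
# is fit to the log10 frequency distribution of intervals; the crossing time
# of the two components is the interval length at which an interval is equally
# likely to belong to either process, which minimizes expected misassignments
# and serves as the BEC.

#' Log-frequency distribution of inter-song-intervals
#'
#' Bins intervals on `[0, max)` with left-closed bins of width `bin_width` and
#' returns the base-10 log of the counts. Empty bins are dropped before the log
#' transform rather than offset with pseudocounts.
#'
#' @param intervals inter-song-intervals in minutes (all positive).
#' @param bin_width bin width in minutes (default 1).
#' @return an object of class `interval_logfreq`: a list with `t` (bin
#'   centres, minutes), `count`, `log10_count` and `bin_width`.
#' @export
interval_log_frequency <- function(intervals, bin_width = 1) {
  intervals <- intervals[is.finite(intervals)]
  if (length(intervals) == 0) stop("no intervals to bin", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (any(intervals <= 0)) stop("intervals must be positive", call. = FALSE)
  hi <- max(ceiling(max(intervals) / bin_width), 1) * bin_width
  breaks <- seq(0, hi, by = bin_width)
  if (max(intervals) >= hi) breaks <- c(breaks, hi + bin_width)
  h <- graphics::hist(intervals, breaks = breaks, plot = FALSE, right = FALSE)
  keep <- h$counts > 0
  structure(list(t = h$mids[keep], count = h$counts[keep],
                 log10_count = log10(h$counts[keep]),
                 bin_width = bin_width, n = length(intervals)),
            class = "interval_logfreq")
}

# Merge sparse histogram bins (empty bins included) until each merged bin
# carries at least min_count events; returns density-normalized counts so the
# exponential count model remains on the base bin-width scale. Removes the
# tail bias that dropping empty bins would otherwise introduce: far out in the
# distribution only occupied bins survive, which flattens the apparent decay.
merge_sparse_bins <- function(t, counts, bin_width, min_count = 3) {
  k <- round(t / bin_width + 0.5)          # 1-based grid index of each centre
  if (max(abs((k - 0.5) * bin_width - t)) > 1e-6 * bin_width)
    return(list(t = t, y = counts, n = counts))   # not on a regular grid
  full <- seq(min(k), max(k))
  cnt <- numeric(length(full))
  cnt[match(k, full)] <- counts
  out_t <- out_y <- out_n <- numeric(0)
  i <- 1
  while (i <= length(full)) {
    j <- i; acc <- cnt[i]
    while (acc < min_count && j < length(full)) {
      j <- j + 1
      acc <- acc + cnt[j]
    }
    if (acc > 0) {
      span <- j - i + 1
      out_t <- c(out_t, bin_width * (full[i] - 1 + span / 2))
      out_y <- c(out_y, acc / span)
      out_n <- c(out_n, acc)
    }
    i <- j + 1
  }
  list(t = out_t, y = out_y, n = out_n)
}

#' Fit a biexponential to an interval log-frequency distribution
#'
#' Nonlinear least squares of the four-parameter biexponential against the
#' binned counts, with squared error measured in log10 space (the fit is to
#' the log frequency distribution) and bins weighted by the square root of
#' their event count (the approximate inverse standard deviation of a log
#' Poisson count). Parameters are estimated on the log scale to enforce
#' positivity.
#'
#' Sparse stretches of the histogram are adaptively rebinned before fitting:
#' adjacent bins — including empty ones — are merged until each merged bin
#' holds at least three events, and the merged counts are normalized back to
#' the base bin width. Without this, dropping empty bins leaves only the
#' occupied tail bins and flattens the apparent slow decay.
#'
#' Initialization: the fast rate from the slope of the first quartile of bins,
#' the slow rate and amplitude from the last quartile, and the fast amplitude
#' by back-projection of the slow component; the optimizer is restarted from
#' ten jittered versions of this start (biexponential least squares is
#' multimodal) and the best residual kept. Restart jitter uses a private RNG
#' stream, so results are deterministic and the caller's RNG is untouched.
#'
#' A fit is only accepted when the data carry evidence of two processes:
#' the rates must be clearly separated (`lambda_f / lambda_s >= 3`; the
#' component crossing is numerically unstable as the rates converge) and the
#' biexponential must at least halve the weighted squared error of the best
#' single-exponential fit.
#'
#' @param t bin centres in minutes, or an `interval_logfreq` object (in which
#'   case `counts` is ignored).
#' @param counts bin counts (all positive; empty bins already dropped).
#' @param n_starts number of jittered restarts (default 10).
#' @param bin_width base bin width in minutes; inferred from an
#'   `interval_logfreq` input or from the spacing of `t` otherwise.
#' @return an object of class `bout_model_fit` with fields `a_f`, `lambda_f`,
#'   `a_s`, `lambda_s` (amplitudes in counts per base bin, rates in 1/min;
#'   relabelled so `lambda_f > lambda_s`), `bec_exact` and `bec` (the
#'   operational nearest-minute value) when the components cross,
#'   `residual_norm`, `converged` and `n_bins`.
#' @examples
#' t <- seq(0.5, 120.5, by = 1)
#' y <- 800 * exp(-0.2 * t) + 20 * exp(-0.01 * t)
#' fit <- fit_biexponential(t, y)
#' bec_from_fit(fit)  # about 19.42 min
#' @export
fit_biexponential <- function(t, counts = NULL, n_starts = 10, bin_width = NULL) {
  if (inherits(t, "interval_logfreq")) {
    counts <- t$count
    bin_width <- bin_width %||% t$bin_width
    t <- t$t
  }
  if (length(t) != length(counts)) stop("t and counts differ in length", call. = FALSE)
  ok <- is.finite(t) & is.finite(counts) & counts > 0
  t <- t[ok]; counts <- counts[ok]
  if (length(t) < 5)
    stop("need at least 5 non-empty bins to fit a biexponential", call. = FALSE)
  ord <- order(t)
  t <- t[ord]; counts <- counts[ord]
  bin_width <- bin_width %||% min(diff(t))

  merged <- merge_sparse_bins(t, counts, bin_width)
  t <- merged$t; y <- merged$y
  w <- sqrt(merged$n)
  nb <- length(t)
  if (nb < 5)
    stop("need at least 5 non-empty bins to fit a biexponential", call. = FALSE)

  # initialization from head/tail slopes of the log distribution
  ly <- log(y)
  nq <- max(3L, ceiling(nb / 4))
  head_ix <- seq_len(nq)
  tail_ix <- seq(nb - nq + 1L, nb)
  slow <- stats::coef(stats::lm(ly[tail_ix] ~ t[tail_ix]))
  lam_s0 <- max(1e-5, -slow[2])
  a_s0 <- max(1e-8, exp(slow[1]))
  head_resid <- pmax(y[head_ix] - a_s0 * exp(-lam_s0 * t[head_ix]),
                     y[head_ix] * 0.02)
  fast <- stats::coef(stats::lm(log(head_resid) ~ t[head_ix]))
  lam_f0 <- max(lam_s0 * 5, -fast[2])
  a_f0 <- max(a_s0, exp(fast[1]))
  par0 <- log(c(a_f0, lam_f0, a_s0, lam_s0))

  resid_fun <- function(p) {
    m <- exp(p[1]) * exp(-exp(p[2]) * t) + exp(p[3]) * exp(-exp(p[4]) * t)
    w * (log10(m) - log10(y))
  }
  best <- NULL
  with_seed(10007L, {
    for (i in seq_len(max(1L, n_starts))) {
      p_init <- if (i == 1) par0 else par0 + stats::rnorm(4, 0, 0.4)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = p_init, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$info %in% 1:4) {
        ssr <- sum(fit$fvec^2)
        if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
      }
    }
  })
  if (is.null(best))
    stop("biexponential fit did not converge", call. = FALSE)
  p <- exp(best$fit$par)
  a <- p[c(1, 3)]; lam <- p[c(2, 4)]
  if (lam[1] < lam[2]) { a <- rev(a); lam <- rev(lam) }

  # evidence guard 1: single-exponential comparison
  single_resid <- function(p) {
    w * (log10(exp(p[1]) * exp(-exp(p[2]) * t)) - log10(y))
  }
  single <- tryCatch(
    minpack.lm::nls.lm(par = log(c(max(y), max(1e-4, 1 / mean(t)))),
                       fn = single_resid,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ssr_single <- if (is.null(single)) Inf else sum(single$fvec^2)
  if (ssr_single < 2 * best$ssr)
    stop("no biexponential structure: a single exponential fits the ",
         "distribution almost as well", call. = FALSE)
  # evidence guard 2: rate separation
  if (lam[2] <= 0 || lam[1] / lam[2] < 3)
    stop("no biexponential structure: fast/slow rate ratio ",
         format(lam[1] / max(lam[2], 1e-12), digits = 3), " < 3", call. = FALSE)
  out <- structure(list(a_f = unname(a[1]), lambda_f = unname(lam[1]),
                        a_s = unname(a[2]), lambda_s = unname(lam[2]),
                        bec_exact = NA_real_, bec = NA_real_,
                        residual_norm = sqrt(best$ssr), converged = TRUE,
                        n_bins = nb),
                   class = "bout_model_fit")
  be <- tryCatch(bec_from_fit(out), error = function(e) NA_real_)
  out$bec_exact <- be
  out$bec <- if (is.finite(be)) round(be) else NA_real_
  out
}

#' @export
print.bout_model_fit <- function(x, ...) {
  cat("Biexponential interval model (counts vs minutes):\n")
  cat(sprintf("  fast: a_f = %.4g, lambda_f = %.4g /min (mean %.2f min)\n",
              x$a_f, x$lambda_f, 1 / x$lambda_f))
  cat(sprintf("  slow: a_s = %.4g, lambda_s = %.4g /min (mean %.2f min)\n",
              x$a_s, x$lambda_s, 1 / x$lambda_s))
  if (is.finite(x$bec_exact))
    cat(sprintf("  BEC: %.2f min (operational %g min)\n", x$bec_exact, x$bec))
  cat(sprintf("  %d bins, residual norm %.4g, converged: %s\n",
              x$n_bins, x$residual_norm, x$converged))
  invisible(x)
}

#' Bout-ending criterion from a biexponential fit
#'
#' The crossing time of the fitted fast and slow components,
#' `t* = ln(a_f / a_s) / (lambda_f - lambda_s)`: the interval length at which
#' an interval is equally likely to come from either process, which minimizes
#' the expected mass of misassigned intervals under the fitted model.
#'
#' `method = "density"` gives the alternative reading in which the fitted
#' amplitudes are taken as component masses rather than count amplitudes, so
#' the crossing is computed on rate-weighted densities,
#' `t = ln(a_f lambda_f / (a_s lambda_s)) / (lambda_f - lambda_s)`. The two
#' differ by `ln(lambda_f/lambda_s)/(lambda_f - lambda_s)` and the difference
#' is surfaced by [bec_diagnostics()].
#'
#' @param fit a `bout_model_fit`.
#' @param method `"crossing"` (default) or `"density"`.
#' @param operational if `TRUE`, round to the nearest minute (the value the
#'   pipeline uses to segment bouts).
#' @return the BEC in minutes.
#' @export
bec_from_fit <- function(fit, method = c("crossing", "density"),
                         operational = FALSE) {
  method <- match.arg(method)
  if (!all(is.finite(c(fit$a_f, fit$a_s, fit$lambda_f, fit$lambda_s))))
    stop("fit parameters are not finite", call. = FALSE)
  if (fit$lambda_f <= fit$lambda_s)
    stop("requires lambda_f > lambda_s", call. = FALSE)
  ratio <- switch(method,
                  crossing = fit$a_f / fit$a_s,
                  density  = (fit$a_f * fit$lambda_f) / (fit$a_s * fit$lambda_s))
  if (ratio <= 1)
    stop("components do not cross at a positive interval (a_f <= a_s)",
         call. = FALSE)
  t_star <- log(ratio) / (fit$lambda_f - fit$lambda_s)
  if (operational) round(t_star) else t_star
}

#' BEC diagnostics
#'
#' Reports the crossing-point and density-reading BEC side by side, plus the
#' sensitivity of the estimate to histogram bin width.
#'
#' @param intervals inter-song-intervals in minutes.
#' @param bin_widths bin widths (minutes) to scan (default `c(0.5, 1, 2)`).
#' @return data frame with one row per bin width: `bin_width`, `n_bins`,
#'   `bec_crossing`, `bec_density` (NA where the fit fails).
#' @export
bec_diagnostics <- function(intervals, bin_widths = c(0.5, 1, 2)) {
  rows <- lapply(bin_widths, function(bw) {
    res <- tryCatch({
      lf <- interval_log_frequency(intervals, bw)
      fit <- fit_biexponential(lf)
      c(length(lf$t), bec_from_fit(fit, "crossing"), bec_from_fit(fit, "density"))
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    data.frame(bin_width = bw, n_bins = res[1],
               bec_crossing = res[2], bec_density = res[3])
  })
  do.call(rbind, rows)
}

#' Estimate the bout-ending criterion from songs
#'
#' Convenience wrapper: pools inter-song-intervals across singers, bins them,
#' fits the biexponential and returns the fit (with the operational BEC in
#' `$bec`).
#'
#' @param songs song table from [assemble_songs()].
#' @param cfg an [analysis_config()] (supplies the bin width).
#' @return a `bout_model_fit`.
#' @export
estimate_bec <- function(songs, cfg = analysis_config()) {
  isi <- inter_song_intervals(songs)
  fit_biexponential(interval_log_frequency(isi, cfg$bin_width))
}

#' Split song sequences into singing bouts
#'
#' A new bout starts at any song whose preceding inter-song-interval is greater
#' than or equal to `bec` minutes (an interval of exactly the BEC splits).
#' Every song belongs to exactly one bout.
#'
#' @param songs song table from [assemble_songs()] (one or many singers).
#' @param bec bout-ending criterion in minutes.
#' @return data frame with one row per bout: `singer_id`, `bout`, `start`,
#'   `end` (epoch seconds), `n_songs` and `duration_s`; the input songs with
#'   their bout index are attached as attribute `"songs"`.
#' @examples
#' songs <- data.frame(singer_id = "A",
#'                     start = c(0, 600, 3000, 3600) * 60,
#'                     end   = c(300, 840, 3300, 3900) * 60)
#' segment_bouts(songs, bec = 35)
#' @export
segment_bouts <- function(songs, bec) {
  stopifnot(is.numeric(bec), length(bec) == 1, bec > 0)
  if (is.null(songs) || nrow(songs) == 0) {
    out <- data.frame(singer_id = character(), bout = integer(),
                      start = numeric(), end = numeric(),
                      n_songs = integer(), duration_s = numeric())
    attr(out, "songs") <- songs
    return(out)
  }
  songs <- songs[order(songs$singer_id, songs$start), , drop = FALSE]
  bout <- unlist(lapply(split(seq_len(nrow(songs)), songs$singer_id), function(ix) {
    n <- length(ix)
    if (n == 1) return(1L)
    gaps <- (songs$start[ix][-1] - songs$end[ix][-n]) / 60
    cumsum(c(1L, as.integer(gaps >= bec)))
  }), use.names = FALSE)
  songs$bout <- bout
  # songs are sorted by singer then start, and bout ids are nondecreasing
  # within singer, so each (singer, bout) group is a contiguous run
  new_grp <- c(TRUE, songs$singer_id[-1] != songs$singer_id[-nrow(songs)] |
                 bout[-1] != bout[-nrow(songs)])
  gid <- cumsum(new_grp)
  first <- which(new_grp)
  last <- c(first[-1] - 1L, nrow(songs))
  agg <- data.frame(singer_id = songs$singer_id[first], bout = bout[first],
                    start = songs$start[first], end = songs$end[last],
                    n_songs = tabulate(gid),
                    duration_s = songs$end[last] - songs$start[first],
                    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  attr(agg, "songs") <- songs
  agg
}

#' Inter-bout-intervals in minutes
#'
#' Silences between successive singing bouts of the same singer (end of one
#' bout to start of the next). By construction each is at least the BEC used
#' to segment the bouts.
#'
#' @param bouts bout table from [segment_bouts()].
#' @return numeric vector of intervals in minutes (empty for single-bout
#'   singers).
#' @export
inter_bout_intervals <- function(bouts) {
  if (is.null(bouts) || nrow(bouts) < 2) return(numeric(0))
  unlist(lapply(split(bouts, bouts$singer_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    if (n < 2) return(numeric(0))
    (d$start[-1] - d$end[-n]) / 60
  }), use.names = FALSE)
}

#' Plot the interval distribution, fitted components and BEC
#'
#' Diagnostic figure: log10 bin counts, the two fitted exponential components,
#' their sum, and a vertical line at the BEC. Written to `file` if given
#' (PNG), otherwise drawn on the current device.
#'
#' @param fit a `bout_model_fit`.
#' @param logfreq the `interval_logfreq` the fit was computed from.
#' @param file optional PNG path.
#' @return the file path (or `NULL`), invisibly.
#' @export
plot_bec_fit <- function(fit, logfreq, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 550)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  t <- logfreq$t
  grid <- seq(min(t), max(t), length.out = 400)
  comp_f <- fit$a_f * exp(-fit$lambda_f * grid)
  comp_s <- fit$a_s * exp(-fit$lambda_s * grid)
  plot(t, logfreq$log10_count, pch = 16, col = "grey30",
       xlab = "inter-song-interval (min)", ylab = "log10 count",
       main = "Interval distribution and biexponential fit")
  graphics::lines(grid, log10(comp_f + comp_s), lwd = 2)
  graphics::lines(grid, log10(pmax(comp_f, 1e-12)), lty = 2, col = "tomato")
  graphics::lines(grid, log10(pmax(comp_s, 1e-12)), lty = 2, col = "steelblue")
  if (is.finite(fit$bec_exact)) {
    graphics::abline(v = fit$bec_exact, lty = 3)
    graphics::mtext(sprintf("BEC = %.1f min", fit$bec_exact), side = 3, adj = 1)
  }
  invisible(file)
}
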