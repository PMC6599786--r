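# Additive smooth models of singing against swimming speed and season.

#' Per-track model table
#'
#' Maps a [track_table()] to the generic model frame expected by
#' [fit_additive_model()]: per-track mean responses and predictors.
#' @param tracks list of `singer_track` objects or a [track_table()].
#' @return data frame with columns `duty_cycle`, `song_duration`, `speed`,
#'   `n_songs`, `day_of_year`, `year` (rows with missing values dropped).
#' @export
model_table <- function(tracks) {
  tt <- if (is.data.frame(tracks)) tracks else track_table(tracks)
  out <- data.frame(duty_cycle = tt$mean_duty_cycle_pct,
                    song_duration = tt$mean_song_duration_min,
                    speed = tt$mean_speed_kmh,
                    n_songs = tt$n_songs,
                    day_of_year = tt$day_of_year,
                    year = tt$year)
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Generalized additive model of singing against speed and season
#'
#' Fits the response (per-track mean duty-cycle or mean song duration) as an
#' additive combination of penalized-regression-spline smooths of swimming
#' speed, number of songs, day-of-year and year, with identity link and
#' Gaussian errors, then performs backward elimination: the least significant
#' smooth is removed one at a time until every retained smooth is significant
#' at `alpha`.
#'
#' Model conventions: day-of-year enters through a cyclic smooth with period
#' 365.25 days so the September-February singing peak can span the year end;
#' year enters as a (thin-plate) smooth over calendar year; basis dimension is
#' `k = 5` per smooth (cohorts here are of order 10^2 tracks and the expected
#' effective degrees of freedom are 3-5), with smoothness chosen by REML.
#' Right-skewed responses and the speed predictor are normalized with the
#' Johnson SL transform (see [fit_johnson_sl()]) when `transform = "auto"`
#' and the sample skewness exceeds `skew_threshold`.
#'
#' @param data model frame from [model_table()] (one row per track; at least
#'   40 rows).
#' @param response `"duty_cycle"` or `"song_duration"`.
#' @param cfg an [analysis_config()] (currently unused hook for thresholds).
#' @param k basis dimension per smooth (default 5).
#' @param alpha significance level for backward elimination (default 0.05).
#' @param transform `"auto"`, `"none"` or `"johnson"` (force).
#' @param skew_threshold sample skewness above which `"auto"` transforms
#'   (default 0.5).
#' @return object of class `additive_model_result`: list with `response`,
#'   `terms` (data frame `variable`, `edf`, `F`, `p_value`), `adj_r2`,
#'   `curves` (per retained smooth: grid `x`, raw-scale `x_raw`, partial
#'   effect `fit` with `se`, `lower`, `upper`), `eliminated` (in removal
#'   order), `intercept_only` flag, transform fits (`response_transform`,
#'   `speed_transform`, possibly `NULL`) and the fitted mgcv model in
#'   `model`.
#' @export
fit_additive_model <- function(data,
                               response = c("duty_cycle", "song_duration"),
                               cfg = analysis_config(), k = 5, alpha = 0.05,
                               transform = c("auto", "none", "johnson"),
                               skew_threshold = 0.5) {
  response <- match.arg(response)
  transform <- match.arg(transform)
  need <- c(response, "speed", "n_songs", "day_of_year", "year")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("model table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  if (nrow(data) < 40)
    stop("need at least 40 tracks to fit the additive model (got ",
         nrow(data), ")", call. = FALSE)

  maybe_transform <- function(x) {
    want <- transform == "johnson" ||
      (transform == "auto" && sample_skewness(x) > skew_threshold)
    if (!want) return(list(fit = NULL, values = x))
    fit <- tryCatch(fit_johnson_sl(x), error = function(e) NULL)
    if (is.null(fit)) list(fit = NULL, values = x)
    else list(fit = fit, values = fit$transformed)
  }
  resp_tr <- maybe_transform(data[[response]])
  speed_tr <- maybe_transform(data$speed)
  dd <- data.frame(y = resp_tr$values, speed = speed_tr$values,
                   n_songs = data$n_songs, day_of_year = data$day_of_year,
                   year = data$year)
  raw_x <- list(speed = data$speed, n_songs = data$n_songs,
                day_of_year = data$day_of_year, year = data$year)

  smooth_term <- function(v) {
    kk <- min(k, length(unique(dd[[v]])))
    switch(v,
           day_of_year = sprintf("s(day_of_year, bs = 'cc', k = %d)", max(kk, 4)),
           sprintf("s(%s, k = %d)", v, kk))
  }
  knots <- list(day_of_year = seq(0, 365.25, length.out = max(min(k, 10), 4)))

  active <- c("speed", "n_songs", "day_of_year", "year")
  # predictors without enough distinct values cannot support a smooth
  active <- active[vapply(active, function(v) length(unique(dd[[v]])) >= 4, TRUE)]
  eliminated <- character(0)
  intercept_only <- FALSE
  model <- NULL
  repeat {
    if (length(active) == 0) {
      model <- mgcv::gam(y ~ 1, data = dd, method = "REML")
      intercept_only <- TRUE
      break
    }
    form <- stats::as.formula(paste("y ~", paste(vapply(active, smooth_term, ""),
                                                 collapse = " + ")))
    kn <- if ("day_of_year" %in% active) knots else NULL
    model <- mgcv::gam(form, data = dd, method = "REML", knots = kn)
    st <- summary(model)$s.table
    pv <- st[, "p-value"]
    vars <- sub("^s\\(([^,)]+).*$", "\\1", rownames(st))
    if (all(pv < alpha)) break
    worst <- vars[which.max(pv)]
    eliminated <- c(eliminated, worst)
    active <- setdiff(active, worst)
  }

  terms_df <- if (intercept_only) {
    data.frame(variable = character(), edf = numeric(), F = numeric(),
               p_value = numeric())
  } else {
    st <- summary(model)$s.table
    data.frame(variable = sub("^s\\(([^,)]+).*$", "\\1", rownames(st)),
               edf = unname(st[, "edf"]), F = unname(st[, "F"]),
               p_value = unname(st[, "p-value"]), stringsAsFactors = FALSE)
  }

  curves <- list()
  if (!intercept_only) {
    meds <- vapply(c("speed", "n_songs", "day_of_year", "year"),
                   function(v) stats::median(dd[[v]]), 0)
    for (v in terms_df$variable) {
      grid <- seq(min(dd[[v]]), max(dd[[v]]), length.out = 100)
      nd <- as.data.frame(as.list(meds))[rep(1, 100), , drop = FALSE]
      nd[[v]] <- grid
      lab <- grep(paste0("^s\\(", v), sapply(model$smooth, `[[`, "label"), value = TRUE)
      pr <- stats::predict(model, newdata = nd, type = "terms",
                           terms = lab, se.fit = TRUE)
      fitv <- as.numeric(pr$fit[, 1]); sev <- as.numeric(pr$se.fit[, 1])
      x_raw <- if (v == "speed" && !is.null(speed_tr$fit))
        johnson_inverse(speed_tr$fit, grid) else grid
      curves[[v]] <- data.frame(x = grid, x_raw = x_raw, fit = fitv, se = sev,
                                lower = fitv - 1.96 * sev,
                                upper = fitv + 1.96 * sev)
    }
  }

  structure(list(response = response, terms = terms_df,
                 adj_r2 = summary(model)$r.sq, curves = curves,
                 eliminated = eliminated, intercept_only = intercept_only,
                 response_transform = resp_tr$fit,
                 speed_transform = speed_tr$fit,
                 n = nrow(dd), model = model),
            class = "additive_model_result")
}

#' @export
print.additive_model_result <- function(x, ...) {
  cat(sprintf("Additive model for %s (n = %d tracks, adj. r2 = %.2f)\n",
              x$response, x$n, x$adj_r2))
  if (x$intercept_only) {
    cat("  all smooths eliminated: intercept-only model\n")
  } else {
    for (i in seq_len(nrow(x$terms)))
      cat(sprintf("  s(%s): edf = %.2f, F = %.2f, p = %.3g\n",
                  x$terms$variable[i], x$terms$edf[i], x$terms$F[i],
                  x$terms$p_value[i]))
  }
  if (length(x$eliminated) > 0)
    cat("  eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  invisible(x)
}

#' Export model tables and partial-effect curves
#'
#' Writes the significance table (variable, d.f., F, p) and, per retained
#' smooth, the sampled partial-effect curve with its confidence band, as CSV.
#' @param fit an `additive_model_result`.
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_model_tables <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p1 <- file.path(dir, paste0(fit$response, "_model_terms.csv"))
  utils::write.csv(fit$terms, p1, row.names = FALSE)
  paths <- c(paths, p1)
  for (v in names(fit$curves)) {
    p <- file.path(dir, paste0(fit$response, "_partial_", v, ".csv"))
    utils::write.csv(fit$curves[[v]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
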