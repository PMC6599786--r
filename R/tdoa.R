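# Hydrophone-array observation model: time-of-arrival forward simulation and
# time-difference-of-arrival (TDOA) multilateration. A generic planar
# formulation — the operational arrays this emulates have classified
# specifications, so the geometry here is user-supplied plumbing for testing
# the localization stage of the pipeline.

#' Hydrophone array geometry
#'
#' @param positions data frame with `array_id`, `x_km`, `y_km` (planar
#'   kilometre grid).
#' @param sound_speed_ms speed of sound (m/s, default 1500).
#' @param toa_noise_sd_s s.d. of Gaussian time-of-arrival noise (seconds).
#' @return object of class `array_geometry`.
#' @export
array_geometry <- function(positions, sound_speed_ms = 1500,
                           toa_noise_sd_s = 0.1) {
  stopifnot(is.data.frame(positions),
            all(c("array_id", "x_km", "y_km") %in% names(positions)),
            sound_speed_ms > 0, toa_noise_sd_s >= 0)
  structure(list(positions = positions, sound_speed_ms = sound_speed_ms,
                 toa_noise_sd_s = toa_noise_sd_s),
            class = "array_geometry")
}

range_km <- function(geom, x, y) {
  sqrt((geom$positions$x_km - x)^2 + (geom$positions$y_km - y)^2)
}

#' Simulate per-array arrival times
#'
#' For each emission, the arrival at each array is the emission time plus the
#' propagation delay (range over sound speed) plus Gaussian noise.
#'
#' @param emissions data frame with `time` (epoch seconds), `x_km`, `y_km`
#'   (and optionally `emission_id`).
#' @param geom an [array_geometry()].
#' @param seed optional integer seed for the noise.
#' @return data frame `emission_id`, `array_id`, `arrival_s`.
#' @export
observe_toa <- function(emissions, geom, seed = NULL) {
  stopifnot(inherits(geom, "array_geometry"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(emissions$emission_id)) emissions$emission_id <- seq_len(nrow(emissions))
  rows <- lapply(seq_len(nrow(emissions)), function(i) {
    r <- range_km(geom, emissions$x_km[i], emissions$y_km[i])
    delay <- r * 1000 / geom$sound_speed_ms
    data.frame(emission_id = emissions$emission_id[i],
               array_id = geom$positions$array_id,
               arrival_s = emissions$time[i] + delay +
                 stats::rnorm(length(delay), 0, geom$toa_noise_sd_s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Localize one emission from arrival times (TDOA multilateration)
#'
#' Nonlinear least squares on arrival times: for a candidate position the
#' emission time is profiled out analytically and the summed squared arrival
#' residual minimized over position. Requires at least three arrays; a
#' collinear array geometry leaves the cross-track coordinate unconstrained
#' and is flagged low-confidence rather than rejected.
#'
#' @param arrivals data frame with `array_id` and `arrival_s` for one
#'   emission.
#' @param geom an [array_geometry()].
#' @return list with `x_km`, `y_km`, `emission_time_s`, `residual_rms_s`,
#'   `low_confidence`.
#' @export
localize_tdoa <- function(arrivals, geom) {
  stopifnot(inherits(geom, "array_geometry"))
  pos <- geom$positions[match(arrivals$array_id, geom$positions$array_id), , drop = FALSE]
  if (nrow(arrivals) < 3 || anyNA(pos$x_km))
    stop("TDOA localization needs arrivals on at least 3 known arrays", call. = FALSE)
  c_ms <- geom$sound_speed_ms
  arr <- arrivals$arrival_s
  obj <- function(p) {
    r <- sqrt((pos$x_km - p[1])^2 + (pos$y_km - p[2])^2) * 1000 / c_ms
    t0 <- mean(arr - r)
    sum((arr - t0 - r)^2)
  }
  init <- c(mean(pos$x_km), mean(pos$y_km))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  r <- sqrt((pos$x_km - fit$par[1])^2 + (pos$y_km - fit$par[2])^2) * 1000 / c_ms
  t0 <- mean(arr - r)
  # collinearity: second principal axis of the array layout carries no spread
  ctr <- scale(as.matrix(pos[, c("x_km", "y_km")]), scale = FALSE)
  sv <- svd(ctr)$d
  low_conf <- sv[1] <= 0 || (sv[2] / sv[1]) < 1e-6
  list(x_km = fit$par[1], y_km = fit$par[2], emission_time_s = t0,
       residual_rms_s = sqrt(fit$value / nrow(arrivals)),
       low_confidence = low_conf)
}

#' Localize many emissions
#'
#' Applies [localize_tdoa()] per emission and returns a localization table in
#' the pipeline's planar schema.
#' @param arrivals data frame from [observe_toa()] (many emissions).
#' @param geom an [array_geometry()].
#' @param singer_id identifier stamped on the output rows.
#' @return data frame `singer_id`, `time` (estimated emission time), `x_km`,
#'   `y_km`, `residual_rms_s`, `low_confidence`.
#' @export
localize_all <- function(arrivals, geom, singer_id = "Fin-001") {
  rows <- lapply(split(arrivals, arrivals$emission_id), function(a) {
    est <- localize_tdoa(a, geom)
    data.frame(singer_id = singer_id, time = est$emission_time_s,
               x_km = est$x_km, y_km = est$y_km,
               residual_rms_s = est$residual_rms_s,
               low_confidence = est$low_confidence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}
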