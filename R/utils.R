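# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so internal randomized
#' routines (e.g. jittered restarts in [fit_biexponential()]) do not perturb
#' user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# moment-based sample skewness; 0 for degenerate input
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Parse times to UTC epoch seconds
#'
#' Accepts numeric epoch seconds or ISO-8601 strings; all file times are
#' interpreted as UTC so arithmetic across midnight and day-of-year boundaries
#' is unambiguous.
#' @noRd
parse_time_utc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  tm <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  as.numeric(tm)
}

# day-of-year (1..366) and calendar year from epoch seconds
epoch_doy <- function(t) as.POSIXlt(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"))$yday + 1
epoch_year <- function(t) as.POSIXlt(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"))$year + 1900

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# spherical Earth radius used throughout (km); localization noise dwarfs
# ellipsoidal corrections at the 10-430 km scales of singer tracks
EARTH_RADIUS_KM <- 6371

#' Great-circle distance between coordinate pairs (km)
#'
#' Haversine distance on a sphere of radius 6371 km, delegated to
#' \pkg{geosphere}. Vectorized over rows.
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84).
#' @return numeric vector of distances in kilometres.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}
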