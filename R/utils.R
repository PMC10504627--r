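# Shared internal helpers: geometry, time binning, seeding, validation.

# Variable order used everywhere downstream. Continuous variables first.
RW_VARS <- c("distance", "steps", "home", "app")
RW_CONT <- c("distance", "steps")
RW_BIN  <- c("home", "app")
RW_NBINS <- 48L
RW_BIN_SECONDS <- 1800L

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km, vectorized over
#' coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distances in meters.
#' @keywords internal
haversine_m <- function(lat1, lon1, lat2, lon2) {
  r <- 6371000
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Seconds since local midnight for POSIXct times (single fixed tz per patient).
seconds_of_day <- function(times) {
  lt <- as.POSIXlt(times)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

# Half-hour bin index (0..47) of a time of day given in seconds.
halfhour_bin <- function(secs) {
  b <- as.integer(floor(secs / RW_BIN_SECONDS))
  pmin(pmax(b, 0L), RW_NBINS - 1L)
}

# Day index (0-based) relative to an enrollment midnight.
day_index <- function(times, origin) {
  as.integer(floor(as.numeric(difftime(times, origin, units = "days"))))
}

# Local midnight of the earliest timestamp.
local_midnight <- function(times) {
  t0 <- min(times)
  lt <- as.POSIXlt(t0)
  lt$hour <- 0L; lt$min <- 0L; lt$sec <- 0
  as.POSIXct(lt)
}

# Reproducible per-patient seed derived from a cohort seed and 0-based index.
# Keeps results independent of generation order and inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * (as.double(index) + 1)) %%
               2147483647)
}

stop_invalid <- function(what, ...) {
  stop(sprintf(what, ...), call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_invalid("%s must lie in [0, 1]", name)
  invisible(x)
}

check_simplex <- function(x, name, tol = 1e-9) {
  if (any(x < -tol)) stop_invalid("%s has negative entries", name)
  if (abs(sum(x) - 1) > tol)
    stop_invalid("%s must sum to 1 (got %.12f)", name, sum(x))
  invisible(x)
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
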