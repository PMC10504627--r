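# Raw sensor logs -> half-hourly daily features. Each monitored day becomes
# four 48-dimensional vectors (one component per 30 minutes): log1p distance
# walked, binary at-home, log1p steps, binary app usage, plus per-bin
# observation masks. Totally missing days are kept as all-missing rows.

#' Infer a patient's home location from night-time GPS fixes
#'
#' Home is the place where the patient spends most time during nights:
#' night-window fixes are binned on a ~50 m grid, each fix weighted by its
#' dwell time (gap to the next night fix, capped at 30 minutes), and the
#' dwell-weighted centroid of the highest-dwell cell is returned. Ties break
#' to the earliest-observed cell.
#'
#' @param gps_fixes data.frame `time, lat, lon` over the whole record.
#' @param night_window two hours `c(start, end)`, default `c(0, 6)`
#'   (00:00-06:00 local).
#' @return a `home_location`: list `lat`, `lon`, `support_nights`.
#' @export
infer_home <- function(gps_fixes, night_window = c(0, 6)) {
  if (nrow(gps_fixes) == 0)
    stop_invalid("home undeterminable: no GPS fixes")
  secs <- seconds_of_day(gps_fixes$time)
  night <- secs >= night_window[1] * 3600 & secs < night_window[2] * 3600
  if (!any(night))
    stop_invalid("home undeterminable: no GPS fixes in the night window")
  nf <- gps_fixes[night, , drop = FALSE]
  nf <- nf[order(nf$time), , drop = FALSE]
  gaps <- c(diff(as.numeric(nf$time)), 300)
  dwell <- pmin(pmax(gaps, 0), RW_BIN_SECONDS)
  # ~50 m grid in local meters
  lat0 <- nf$lat[1]
  cell <- paste(floor(nf$lat * M_PER_DEG / 50),
                floor(nf$lon * M_PER_DEG * cos(lat0 * pi / 180) / 50))
  dw <- tapply(dwell, cell, sum)
  first_seen <- tapply(seq_len(nrow(nf)), cell, min)
  best <- names(dw)[order(-dw, first_seen)][1]
  sel <- cell == best
  w <- dwell[sel] / sum(dwell[sel])
  nights <- length(unique(as.Date(nf$time[sel], tz = "UTC")))
  structure(list(lat = sum(nf$lat[sel] * w), lon = sum(nf$lon[sel] * w),
                 support_nights = max(1L, nights)),
            class = "home_location")
}

#' Half-hourly distance walked for one day
#'
#' Per-bin value is `log1p` of the summed haversine distances (meters)
#' between consecutive fixes whose segment midpoint falls in the bin. Bins
#' containing no fix are flagged missing.
#'
#' @param gps_fixes data.frame `time, lat, lon` for a single day, sorted.
#' @return list `value` (48 reals, log1p meters) and `mask` (48 logicals).
#' @export
bin_distance <- function(gps_fixes) {
  value <- rep(NA_real_, RW_NBINS)
  mask <- rep(FALSE, RW_NBINS)
  n <- nrow(gps_fixes)
  if (n == 0) return(list(value = value, mask = mask))
  secs <- seconds_of_day(gps_fixes$time)
  mask[unique(halfhour_bin(secs)) + 1L] <- TRUE
  meters <- rep(0, RW_NBINS)
  if (n > 1) {
    seg <- haversine_m(gps_fixes$lat[-n], gps_fixes$lon[-n],
                       gps_fixes$lat[-1], gps_fixes$lon[-1])
    mid_bin <- halfhour_bin((secs[-n] + secs[-1]) / 2)
    agg <- tapply(seg, mid_bin, sum)
    meters[as.integer(names(agg)) + 1L] <- agg
  }
  value[mask] <- log1p(meters[mask])
  list(value = value, mask = mask)
}

#' Half-hourly at-home indicator for one day
#'
#' A bin is 1 if any fix in it lies within `radius_m` of home and 0 if all
#' its fixes are farther away; bins with no fix are missing.
#'
#' @param gps_fixes data.frame `time, lat, lon` for one day.
#' @param home a `home_location` from [infer_home()].
#' @param radius_m at-home radius in meters (default 200, absorbing urban
#'   GPS noise).
#' @return list `value` (48 binaries) and `mask`.
#' @export
bin_home <- function(gps_fixes, home, radius_m = 200) {
  value <- rep(NA_real_, RW_NBINS)
  mask <- rep(FALSE, RW_NBINS)
  if (nrow(gps_fixes) == 0) return(list(value = value, mask = mask))
  b <- halfhour_bin(seconds_of_day(gps_fixes$time))
  near <- haversine_m(gps_fixes$lat, gps_fixes$lon, home$lat, home$lon) <=
    radius_m
  at_home <- tapply(near, b, any)
  idx <- as.integer(names(at_home)) + 1L
  mask[idx] <- TRUE
  value[idx] <- as.numeric(at_home)
  list(value = value, mask = mask)
}

#' Half-hourly step counts for one day
#'
#' Per-bin `log1p` of the total steps recorded in the bin. The step source is
#' heartbeat-based: if the day has at least one step record (zero counts
#' included), every bin is observed (absent bins are true zeros); with no
#' record at all the whole day is missing for this variable.
#'
#' @param step_events data.frame `time, steps` for one day.
#' @return list `value` (48 reals, log1p steps) and `mask`.
#' @export
bin_steps <- function(step_events) {
  if (nrow(step_events) == 0)
    return(list(value = rep(NA_real_, RW_NBINS), mask = rep(FALSE, RW_NBINS)))
  if (any(step_events$steps < 0))
    stop_invalid("step counts must be >= 0")
  counts <- rep(0, RW_NBINS)
  b <- halfhour_bin(seconds_of_day(step_events$time))
  agg <- tapply(step_events$steps, b, sum)
  counts[as.integer(names(agg)) + 1L] <- agg
  list(value = log1p(counts), mask = rep(TRUE, RW_NBINS))
}

#' Half-hourly app usage for one day
#'
#' A bin is 1 if at least one app event falls in it. Observability follows
#' the heartbeat rule: with at least one app event that day, all bins are
#' observed (a 0 is a true non-use); a day with no app event at all is
#' missing — indistinguishable from a dead phone.
#'
#' @param app_events data.frame `time` for one day.
#' @return list `value` (48 binaries) and `mask`.
#' @export
bin_app_usage <- function(app_events) {
  if (nrow(app_events) == 0)
    return(list(value = rep(NA_real_, RW_NBINS), mask = rep(FALSE, RW_NBINS)))
  value <- rep(0, RW_NBINS)
  value[unique(halfhour_bin(seconds_of_day(app_events$time))) + 1L] <- 1
  list(value = value, mask = rep(TRUE, RW_NBINS))
}

#' Build the daily feature matrix from a raw stream
#'
#' Composes home inference and the four per-day binning operations over every
#' calendar day from the first to the last observation (or over
#' `0..n_days-1` when `n_days` is given, preserving trailing/leading totally
#' missing days). If home cannot be inferred, the home variable is fully
#' missing and the rest proceeds.
#'
#' @param stream a [raw_stream()].
#' @param night_window,home_radius_m home-inference parameters, see
#'   [infer_home()] and [bin_home()].
#' @param n_days force the number of days (0-based indices `0..n_days-1`
#'   from the stream origin); default spans the observations.
#' @return a [daily_features()] object.
#' @export
build_daily_features <- function(stream, night_window = c(0, 6),
                                 home_radius_m = 200, n_days = NULL) {
  all_t <- c(stream$gps$time, stream$steps$time, stream$app$time)
  origin <- stream$origin
  if (is.null(origin) && length(all_t) > 0) origin <- local_midnight(all_t)
  if (is.null(n_days)) {
    n_days <- if (length(all_t) == 0) 0L
    else max(day_index(all_t, origin)) + 1L
  }
  d <- as.integer(n_days)
  mats <- lapply(RW_VARS, function(v) matrix(NA_real_, d, RW_NBINS))
  names(mats) <- RW_VARS
  mask <- lapply(RW_VARS, function(v) matrix(FALSE, d, RW_NBINS))
  names(mask) <- RW_VARS
  if (d == 0) {
    return(daily_features(stream$patient_id, integer(0), mats$distance,
                          mats$steps, mats$home, mats$app, mask))
  }
  home <- tryCatch(infer_home(stream$gps, night_window), error = function(e) NULL)
  split_by_day <- function(df) {
    if (nrow(df) == 0) return(vector("list", d))
    di <- day_index(df$time, origin)
    ok <- di >= 0 & di < d
    split(df[ok, , drop = FALSE], factor(di[ok], levels = 0:(d - 1)))
  }
  gps_by <- split_by_day(stream$gps)
  steps_by <- split_by_day(stream$steps)
  app_by <- split_by_day(stream$app)
  nilrow <- function(df, proto) if (is.null(df)) proto[0, , drop = FALSE] else df
  for (i in seq_len(d)) {
    g <- nilrow(gps_by[[i]], stream$gps)
    bd <- bin_distance(g)
    mats$distance[i, ] <- bd$value; mask$distance[i, ] <- bd$mask
    if (!is.null(home)) {
      bh <- bin_home(g, home, home_radius_m)
      mats$home[i, ] <- bh$value; mask$home[i, ] <- bh$mask
    }
    bs <- bin_steps(nilrow(steps_by[[i]], stream$steps))
    mats$steps[i, ] <- bs$value; mask$steps[i, ] <- bs$mask
    ba <- bin_app_usage(nilrow(app_by[[i]], stream$app))
    mats$app[i, ] <- ba$value; mask$app[i, ] <- ba$mask
  }
  daily_features(stream$patient_id, 0:(d - 1), mats$distance, mats$steps,
                 mats$home, mats$app, mask)
}
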