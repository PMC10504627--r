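# DailyFeatureMatrix container: four 48-bin variables per day plus an
# observation mask. Rows are calendar days (0-based index from enrollment),
# never dropped: totally missing days stay as all-missing rows so the
# change-point stage can marginalize them.

#' Construct a daily feature matrix
#'
#' The per-day observation unit of the pipeline: for each monitored day, four
#' 48-dimensional half-hourly vectors (one component per 30 minutes) —
#' log-distance walked, binary at-home indicator, log-steps, binary app usage
#' — together with a per-bin observation mask.
#'
#' @param patient_id identifier.
#' @param days integer vector of 0-based day indices from enrollment.
#' @param distance,steps numeric day x 48 matrices on the log1p scale.
#' @param home,app binary day x 48 matrices (0/1 where observed).
#' @param mask named list of logical day x 48 matrices
#'   (`distance`, `steps`, `home`, `app`); `TRUE` means observed.
#' @return an object of class `daily_features`.
#' @export
daily_features <- function(patient_id, days, distance, steps, home, app, mask) {
  mats <- list(distance = distance, steps = steps, home = home, app = app)
  d <- length(days)
  for (v in RW_VARS) {
    m <- mats[[v]]
    if (!is.matrix(m) || nrow(m) != d || ncol(m) != RW_NBINS)
      stop_invalid("variable '%s' must be a %d x 48 matrix", v, d)
    if (!is.matrix(mask[[v]]) || nrow(mask[[v]]) != d ||
        ncol(mask[[v]]) != RW_NBINS)
      stop_invalid("mask for '%s' must be a %d x 48 logical matrix", v, d)
    obs <- mask[[v]] & is.finite(m)
    if (v %in% RW_BIN && any(!(m[obs] %in% c(0, 1))))
      stop_invalid("binary variable '%s' takes values outside {0,1}", v)
  }
  structure(list(patient_id = patient_id, days = as.integer(days),
                 distance = distance, steps = steps, home = home, app = app,
                 mask = mask),
            class = "daily_features")
}

#' @export
print.daily_features <- function(x, ...) {
  obs <- mean(vapply(x$mask, mean, numeric(1)))
  cat(sprintf("<daily_features> patient %s: %d days, %.1f%% bins observed\n",
              x$patient_id, length(x$days), 100 * obs))
  invisible(x)
}

n_days <- function(features) length(features$days)

# Flatten to the 192-dimensional model layout: continuous block (distance,
# steps -> 96 dims) and binary block (home, app -> 96 dims), with masks.
flatten_features <- function(features) {
  list(
    xc = cbind(features$distance, features$steps),
    xb = cbind(features$home, features$app),
    mc = cbind(features$mask$distance, features$mask$steps),
    mb = cbind(features$mask$home, features$mask$app)
  )
}

# Fraction of the 192 bins observed, per day.
observed_fraction <- function(features) {
  tot <- Reduce(`+`, lapply(features$mask, rowSums))
  tot / (4 * RW_NBINS)
}

#' Identify totally missing days
#'
#' A day is treated as totally missing for profiling when fewer than
#' `min_obs_frac` of its 192 bins are observed across all four variables.
#'
#' @param features a [daily_features()] object.
#' @param min_obs_frac minimum observed fraction for a day to be usable.
#' @return logical vector, `TRUE` where the day is treated as missing.
#' @export
totally_missing_days <- function(features, min_obs_frac = 0.1) {
  observed_fraction(features) < min_obs_frac
}

#' Write daily features as tidy CSV
#'
#' One row per (day, variable, bin): `patient_id, day, variable, bin, value,
#' observed`.
#'
#' @param features a [daily_features()] object.
#' @param path output CSV path.
#' @export
write_features_csv <- function(features, path) {
  d <- length(features$days)
  out <- do.call(rbind, lapply(RW_VARS, function(v) {
    data.frame(
      patient_id = features$patient_id,
      day = rep(features$days, RW_NBINS),
      variable = v,
      bin = rep(0:(RW_NBINS - 1L), each = d),
      value = as.vector(features[[v]]),
      observed = as.vector(features$mask[[v]])
    )
  }))
  out <- out[order(out$day, out$variable, out$bin), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read daily features from tidy CSV
#'
#' Inverse of [write_features_csv()].
#'
#' @param path CSV path.
#' @return a [daily_features()] object.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  days <- sort(unique(df$day))
  d <- length(days)
  mats <- list(); mask <- list()
  for (v in RW_VARS) {
    sub <- df[df$variable == v, ]
    m <- matrix(NA_real_, d, RW_NBINS)
    o <- matrix(FALSE, d, RW_NBINS)
    i <- match(sub$day, days)
    j <- sub$bin + 1L
    m[cbind(i, j)] <- sub$value
    o[cbind(i, j)] <- sub$observed
    m[!o] <- NA_real_
    mats[[v]] <- m; mask[[v]] <- o
  }
  daily_features(df$patient_id[1], days, mats$distance, mats$steps,
                 mats$home, mats$app, mask)
}
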