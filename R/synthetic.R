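# Synthetic cohort generator. Produces per-patient raw sensor streams (GPS
# fixes every 5 minutes, per-bin step counts, app-usage events) whose
# half-hourly aggregation follows per-profile emission parameters, plus the
# ground truth needed for evaluation: latent daily profile labels,
# piecewise-constant behavioral patterns separated by planted change points,
# risk events temporally coupled to change points, and partial/total
# missingness.
#
# Day structure: bins 0..13 (00:00-07:00) are a common "night" block (at
# home, asleep, sporadic app checks); behavioral profiles govern the 34
# daytime bins. Each daytime bin is independently spent at home or away;
# away bins accrue random-walk GPS displacement scaled to the profile's
# target per-bin distance, and step counts are Poisson with profile-specific
# rates.

NIGHT_BINS <- 0:13
DAY_BINS <- 14:47
FIXES_PER_BIN <- 6L                     # one GPS fix per 5 minutes

#' Behavioral profile emission parameters
#'
#' Parameters of one latent daily profile for the synthetic generator.
#'
#' @param name label (descriptive only, e.g. "high_activity").
#' @param p_home_day probability a daytime half-hour bin is spent at home.
#' @param away_dist_m target distance walked per away bin, meters.
#' @param steps_away,steps_home Poisson step-count rates per away / at-home
#'   daytime bin.
#' @param p_app_day,p_app_night probability of using any app in a daytime /
#'   night bin.
#' @return a `profile_params` list.
#' @export
profile_params <- function(name, p_home_day, away_dist_m, steps_away,
                           steps_home, p_app_day, p_app_night = 0.05) {
  check_prob(c(p_home_day, p_app_day, p_app_night), "profile probabilities")
  if (away_dist_m < 0 || steps_away < 0 || steps_home < 0)
    stop_invalid("profile rates must be non-negative")
  structure(list(name = name, p_home_day = p_home_day,
                 away_dist_m = away_dist_m, steps_away = steps_away,
                 steps_home = steps_home, p_app_day = p_app_day,
                 p_app_night = p_app_night),
            class = "profile_params")
}

#' Default high/low-activity profile pair
#'
#' A patient alternating between these two profiles reproduces the canonical
#' worked scenario: mostly-out, high-step days versus mostly-home, low-step,
#' high-phone-use days.
#'
#' @return named list of two [profile_params()].
#' @export
default_profiles <- function() {
  list(
    high_activity = profile_params("high_activity", p_home_day = 0.25,
                                   away_dist_m = 500, steps_away = 800,
                                   steps_home = 60, p_app_day = 0.35),
    low_activity = profile_params("low_activity", p_home_day = 0.9,
                                  away_dist_m = 150, steps_away = 300,
                                  steps_home = 25, p_app_day = 0.75)
  )
}

#' Synthetic cohort scenario configuration
#'
#' Describes a generative world: the latent profiles, the piecewise-constant
#' behavioral patterns (segments) they are drawn from, the coupling of risk
#' events to planted change points, and the missingness rates.
#'
#' @param n_patients cohort size.
#' @param days_per_patient monitored days per patient.
#' @param profiles list of [profile_params()] (at most 10).
#' @param segments list of `list(start_day =, profile_dist =)` defining the
#'   behavioral patterns; `start_day`s strictly increasing, first must be 0,
#'   each `profile_dist` a simplex over profiles. Days in `[start_day, next)`
#'   draw their profile from that distribution.
#' @param event_lag_days days from a planted change point to its coupled risk
#'   event (default 3, inside the 7-day alarm window).
#' @param p_event_given_change probability a planted change point is followed
#'   by a risk event (benign changes otherwise).
#' @param p_background_event probability a patient suffers a risk event
#'   unrelated to any change point (placed uniformly at random).
#' @param p_attempt probability a risk event is a suicide attempt rather
#'   than a psychiatric ED visit (default 18/32, the attempt share among
#'   events).
#' @param partial_missing_rate probability each (day, sensor source) is
#'   dropped; the GPS source carries both the distance and home variables.
#' @param total_missing_rate probability a whole day records nothing.
#' @param rng_seed cohort master seed; per-patient seeds are derived from it.
#' @return a validated `scenario_config`.
#' @export
scenario_config <- function(n_patients = 10,
                            days_per_patient = 120,
                            profiles = default_profiles(),
                            segments = list(
                              list(start_day = 0,
                                   profile_dist = c(5, 2) / 7),
                              list(start_day = 60,
                                   profile_dist = c(2, 5) / 7)),
                            event_lag_days = 3,
                            p_event_given_change = 0.5,
                            p_background_event = 0.05,
                            p_attempt = 18 / 32,
                            partial_missing_rate = 0,
                            total_missing_rate = 0,
                            rng_seed = 1) {
  cfg <- structure(list(n_patients = as.integer(n_patients),
                        days_per_patient = as.integer(days_per_patient),
                        profiles = profiles, segments = segments,
                        event_lag_days = as.integer(event_lag_days),
                        p_event_given_change = p_event_given_change,
                        p_background_event = p_background_event,
                        p_attempt = p_attempt,
                        partial_missing_rate = partial_missing_rate,
                        total_missing_rate = total_missing_rate,
                        rng_seed = as.integer(rng_seed)),
                   class = "scenario_config")
  validate_scenario(cfg)
}

#' Validate a scenario configuration
#'
#' Checks every structural invariant and fails naming the violated one.
#'
#' @param config a `scenario_config`.
#' @return the config, invisibly usable.
#' @export
validate_scenario <- function(config) {
  if (config$n_patients < 0) stop_invalid("n_patients must be >= 0")
  if (config$days_per_patient < 0) stop_invalid("days_per_patient must be >= 0")
  k <- length(config$profiles)
  if (k < 1 || k > 10) stop_invalid("number of profiles must be in 1..10")
  starts <- vapply(config$segments, function(s) s$start_day, numeric(1))
  if (length(starts) == 0 || starts[1] != 0)
    stop_invalid("first segment must start at day 0")
  if (any(diff(starts) <= 0))
    stop_invalid("segment start_days must be strictly increasing")
  for (s in config$segments) {
    if (length(s$profile_dist) != k)
      stop_invalid("profile_dist length must match number of profiles")
    check_simplex(s$profile_dist, "profile_dist")
  }
  check_prob(c(config$p_event_given_change, config$p_background_event,
               config$p_attempt, config$partial_missing_rate,
               config$total_missing_rate), "rates")
  if (config$event_lag_days < 0) stop_invalid("event_lag_days must be >= 0")
  config
}

#' Construct a raw sensor stream
#'
#' @param patient_id identifier.
#' @param gps data.frame `time` (POSIXct), `lat`, `lon` (degrees).
#' @param steps data.frame `time`, `steps` (count, may be 0 = heartbeat).
#' @param app data.frame `time`.
#' @param origin enrollment midnight (POSIXct); inferred from the earliest
#'   observation when `NULL`.
#' @return a `raw_stream`.
#' @export
raw_stream <- function(patient_id, gps, steps, app, origin = NULL) {
  for (d in list(gps, steps, app)) {
    if (nrow(d) > 1 && is.unsorted(d$time))
      stop_invalid("timestamps must be non-decreasing within each sensor")
  }
  if (nrow(gps) > 0 &&
      (any(abs(gps$lat) > 90) || any(abs(gps$lon) > 180)))
    stop_invalid("GPS coordinates out of range")
  if (nrow(steps) > 0 && any(steps$steps < 0))
    stop_invalid("step counts must be >= 0")
  if (is.null(origin)) {
    all_t <- c(gps$time, steps$time, app$time)
    origin <- if (length(all_t)) local_midnight(all_t) else NULL
  }
  structure(list(patient_id = patient_id, gps = gps, steps = steps,
                 app = app, origin = origin),
            class = "raw_stream")
}

#' @export
print.raw_stream <- function(x, ...) {
  cat(sprintf("<raw_stream> patient %s: %d GPS fixes, %d step records, %d app events\n",
              x$patient_id, nrow(x$gps), nrow(x$steps), nrow(x$app)))
  invisible(x)
}

empty_stream <- function(patient_id, origin = NULL) {
  raw_stream(patient_id,
             gps = data.frame(time = as.POSIXct(character(), tz = "UTC"),
                              lat = numeric(), lon = numeric()),
             steps = data.frame(time = as.POSIXct(character(), tz = "UTC"),
                                steps = numeric()),
             app = data.frame(time = as.POSIXct(character(), tz = "UTC")),
             origin = origin)
}

# Latent profile label per day (1-based), from the piecewise-constant
# segment distributions. Uses the current RNG state.
sample_labels <- function(config) {
  d <- config$days_per_patient
  if (d == 0) return(integer(0))
  starts <- vapply(config$segments, function(s) s$start_day, numeric(1))
  seg_of_day <- findInterval(0:(d - 1), starts)
  vapply(seq_len(d), function(i) {
    dist <- config$segments[[seg_of_day[i]]]$profile_dist
    sample.int(length(dist), 1, prob = dist)
  }, integer(1))
}

# ~111 km per degree latitude; used to convert meter offsets to degrees.
M_PER_DEG <- 111320

# Generate one day of raw records for a given profile. Returns list of
# data.frames (gps, steps, app). day0: POSIXct midnight of the day.
generate_day <- function(day0, prof, home_lat, home_lon) {
  at_home_bin <- rep(TRUE, RW_NBINS)
  at_home_bin[DAY_BINS + 1] <-
    stats::runif(length(DAY_BINS)) < prof$p_home_day
  n_fix <- RW_NBINS * FIXES_PER_BIN
  fix_bin <- rep(0:(RW_NBINS - 1L), each = FIXES_PER_BIN)
  times <- day0 + (seq_len(n_fix) - 1) * 300
  lat <- numeric(n_fix); lon <- numeric(n_fix)
  step_m <- prof$away_dist_m / FIXES_PER_BIN
  away <- FALSE
  cur_lat <- home_lat; cur_lon <- home_lon
  for (i in seq_len(n_fix)) {
    b <- fix_bin[i] + 1L
    if (at_home_bin[b]) {
      away <- FALSE
      cur_lat <- home_lat + stats::rnorm(1, 0, 10 / M_PER_DEG)
      cur_lon <- home_lon + stats::rnorm(1, 0, 10 / M_PER_DEG)
    } else {
      if (!away) {                     # leave home: 800 m excursion base
        th <- stats::runif(1, 0, 2 * pi)
        cur_lat <- home_lat + 800 * sin(th) / M_PER_DEG
        cur_lon <- home_lon + 800 * cos(th) / M_PER_DEG
        away <- TRUE
      } else {                         # random-walk displacement
        th <- stats::runif(1, 0, 2 * pi)
        cur_lat <- cur_lat + step_m * sin(th) / M_PER_DEG
        cur_lon <- cur_lon + step_m * cos(th) / M_PER_DEG
        # keep excursions clear of the 200 m home radius
        d_home <- sqrt(((cur_lat - home_lat) * M_PER_DEG)^2 +
                         ((cur_lon - home_lon) * M_PER_DEG)^2)
        if (d_home < 400) {
          scale <- 800 / max(d_home, 1)
          cur_lat <- home_lat + (cur_lat - home_lat) * scale
          cur_lon <- home_lon + (cur_lon - home_lon) * scale
        }
      }
    }
    lat[i] <- cur_lat; lon[i] <- cur_lon
  }
  rate <- ifelse(at_home_bin[DAY_BINS + 1], prof$steps_home, prof$steps_away)
  step_counts <- integer(RW_NBINS)
  step_counts[DAY_BINS + 1] <- stats::rpois(length(DAY_BINS), rate)
  p_app <- rep(prof$p_app_night, RW_NBINS)
  p_app[DAY_BINS + 1] <- prof$p_app_day
  app_bins <- which(stats::runif(RW_NBINS) < p_app) - 1L
  list(
    gps = data.frame(time = times, lat = lat, lon = lon),
    steps = data.frame(time = day0 + (0:(RW_NBINS - 1L)) * 1800 + 60,
                       steps = step_counts),
    app = data.frame(time = day0 + app_bins * 1800 + 900)
  )
}

#' Generate one synthetic patient
#'
#' Draws a latent profile label for each day from the active behavioral
#' pattern, emits the raw sensor records for that profile, plants risk
#' events `event_lag_days` after (a configurable fraction of) change points
#' plus background events uncoupled to any change, and applies missingness.
#' Deterministic given `(config, patient_seed)`.
#'
#' @param config a [scenario_config()].
#' @param patient_seed integer seed for this patient.
#' @param patient_id identifier (default derived from the seed).
#' @return list with `stream` (a [raw_stream()]) and `truth` (list:
#'   `labels` per-day latent profile, `change_points` 0-based day indices,
#'   `events` data.frame `day, type`, `missing` day x 4 logical matrix of
#'   removed variable-days, columns distance/steps/home/app).
#' @export
generate_patient <- function(config, patient_seed,
                             patient_id = paste0("P", patient_seed)) {
  validate_scenario(config)
  d <- config$days_per_patient
  origin <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  miss0 <- matrix(FALSE, d, 4,
                  dimnames = list(NULL, c("distance", "steps", "home", "app")))
  if (d == 0) {
    return(list(stream = empty_stream(patient_id, origin),
                truth = list(labels = integer(0), change_points = integer(0),
                             events = data.frame(day = integer(),
                                                 type = character()),
                             missing = miss0)))
  }
  set.seed(patient_seed)
  labels <- sample_labels(config)
  starts <- vapply(config$segments, function(s) s$start_day, numeric(1))
  cps <- as.integer(starts[starts > 0 & starts < d])
  home_lat <- 40.4 + stats::rnorm(1, 0, 0.05)
  home_lon <- -3.7 + stats::rnorm(1, 0, 0.05)
  recs <- lapply(seq_len(d), function(i)
    generate_day(origin + (i - 1) * 86400, config$profiles[[labels[i]]],
                 home_lat, home_lon))
  stream <- raw_stream(
    patient_id,
    gps = do.call(rbind, lapply(recs, `[[`, "gps")),
    steps = do.call(rbind, lapply(recs, `[[`, "steps")),
    app = do.call(rbind, lapply(recs, `[[`, "app")),
    origin = origin)
  # risk events: coupled to change points, plus background events
  ev_day <- integer(0)
  for (cp in cps) {
    if (stats::runif(1) < config$p_event_given_change) {
      e <- cp + config$event_lag_days
      if (e < d) ev_day <- c(ev_day, e)
    }
  }
  if (stats::runif(1) < config$p_background_event && d > 1)
    ev_day <- c(ev_day, sample.int(d, 1) - 1L)
  ev_day <- sort(unique(ev_day))
  ev_type <- ifelse(stats::runif(length(ev_day)) < config$p_attempt,
                    "suicide_attempt", "ed_visit")
  events <- data.frame(day = as.integer(ev_day), type = ev_type,
                       stringsAsFactors = FALSE)
  inj <- inject_missingness(stream, config)
  list(stream = inj$stream,
       truth = list(labels = labels, change_points = cps, events = events,
                    missing = inj$missing))
}

#' Remove observations to emulate partial and total missingness
#'
#' Each day is dropped entirely with probability `total_missing_rate`;
#' otherwise each sensor source (GPS, steps, app) of each day is dropped
#' independently with probability `partial_missing_rate`. Dropping the GPS
#' source makes both the distance and home variables missing. Uses the
#' current RNG state (seed it for reproducibility).
#'
#' @param stream a [raw_stream()].
#' @param config a [scenario_config()] (only the two rates are used).
#' @return list with the thinned `stream` and `missing`, a day x 4 logical
#'   matrix (columns distance/steps/home/app) of removed variable-days.
#' @export
inject_missingness <- function(stream, config) {
  check_prob(c(config$partial_missing_rate, config$total_missing_rate),
             "missingness rates")
  d <- config$days_per_patient
  miss <- matrix(FALSE, d, 4,
                 dimnames = list(NULL, c("distance", "steps", "home", "app")))
  if (d == 0 ||
      (config$partial_missing_rate == 0 && config$total_missing_rate == 0))
    return(list(stream = stream, missing = miss))
  total <- stats::runif(d) < config$total_missing_rate
  drop_src <- matrix(stats::runif(3 * d) < config$partial_missing_rate, d, 3,
                     dimnames = list(NULL, c("gps", "steps", "app")))
  drop_src[total, ] <- TRUE
  miss[, "distance"] <- miss[, "home"] <- drop_src[, "gps"]
  miss[, "steps"] <- drop_src[, "steps"]
  miss[, "app"] <- drop_src[, "app"]
  keep <- function(df, src) {
    if (nrow(df) == 0) return(df)
    di <- day_index(df$time, stream$origin) + 1L
    ok <- di >= 1 & di <= d
    ok[ok] <- !drop_src[di[ok], src]
    df[ok, , drop = FALSE]
  }
  stream2 <- raw_stream(stream$patient_id,
                        gps = keep(stream$gps, "gps"),
                        steps = keep(stream$steps, "steps"),
                        app = keep(stream$app, "app"),
                        origin = stream$origin)
  list(stream = stream2, missing = miss)
}

#' Generate a synthetic cohort
#'
#' Per-patient seeds are derived reproducibly from the cohort seed and the
#' 0-based patient index, so the cohort is deterministic given the config and
#' independent of generation order.
#'
#' @param config a [scenario_config()].
#' @return list of `list(stream =, truth =)`, length `n_patients`.
#' @export
generate_cohort <- function(config) {
  validate_scenario(config)
  lapply(seq_len(config$n_patients), function(i)
    generate_patient(config, derive_seed(config$rng_seed, i - 1L),
                     patient_id = sprintf("P%03d", i)))
}

#' Simulate daily features directly from mixture emissions
#'
#' Model-space shortcut that skips the raw-stream and preprocessing stages:
#' draws each day's 192-bin feature vector straight from per-profile Gaussian
#' (continuous block) and Bernoulli (binary block) emission distributions.
#' Used to study the profiling and change-point stages in isolation.
#'
#' @param labels integer vector of per-day latent profile labels (1-based).
#' @param mu,sigma K x 96 matrices (or K-vectors, recycled across bins) of
#'   Gaussian means / standard deviations for the continuous block.
#' @param p K x 96 matrix (or K-vector) of Bernoulli probabilities for the
#'   binary block.
#' @param seed RNG seed.
#' @param patient_id identifier.
#' @return a [daily_features()] with everything observed.
#' @export
simulate_features <- function(labels, mu, sigma, p, seed = 1,
                              patient_id = "sim") {
  k <- max(labels)
  expand <- function(x) {
    if (is.matrix(x)) x else matrix(x, k, 96)
  }
  mu <- expand(mu); sigma <- expand(sigma); p <- expand(p)
  d <- length(labels)
  set.seed(seed)
  xc <- mu[labels, , drop = FALSE] +
    matrix(stats::rnorm(d * 96), d, 96) * sigma[labels, , drop = FALSE]
  xb <- matrix(as.numeric(matrix(stats::runif(d * 96), d, 96) <
                            p[labels, , drop = FALSE]), d, 96)
  ones <- matrix(TRUE, d, RW_NBINS)
  daily_features(patient_id, seq_len(d) - 1L,
                 distance = xc[, 1:48, drop = FALSE],
                 steps = xc[, 49:96, drop = FALSE],
                 home = xb[, 1:48, drop = FALSE],
                 app = xb[, 49:96, drop = FALSE],
                 mask = list(distance = ones, steps = ones,
                             home = ones, app = ones))
}

#' Write a raw stream as JSONL
#'
#' One JSON record per sensor observation:
#' `{"patient_id":, "timestamp":, "sensor": "gps"|"steps"|"app", "payload":}`.
#'
#' @param stream a [raw_stream()].
#' @param path output path.
#' @export
write_stream_jsonl <- function(stream, path) {
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(ts, sensor, payload) {
    n <- length(ts)
    if (n == 0) return(invisible())
    lines <- vapply(seq_len(n), function(i)
      jsonlite::toJSON(list(patient_id = stream$patient_id,
                            timestamp = ts[i], sensor = sensor,
                            payload = payload[[i]]),
                       auto_unbox = TRUE, digits = NA), character(1))
    writeLines(lines, con)
  }
  emit(iso(stream$gps$time), "gps",
       lapply(seq_len(nrow(stream$gps)), function(i)
         list(lat = stream$gps$lat[i], lon = stream$gps$lon[i])))
  emit(iso(stream$steps$time), "steps",
       lapply(stream$steps$steps, function(s) list(steps = s)))
  emit(iso(stream$app$time), "app",
       rep(list(structure(list(), names = character())), nrow(stream$app)))
  invisible(path)
}

#' Read a raw stream from JSONL
#'
#' Inverse of [write_stream_jsonl()].
#'
#' @param path JSONL path.
#' @return a [raw_stream()].
#' @export
read_stream_jsonl <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE, flatten = TRUE)
  if (nrow(df) == 0) return(empty_stream("unknown"))
  t <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ord <- order(t)
  df <- df[ord, , drop = FALSE]; t <- t[ord]
  g <- df$sensor == "gps"; s <- df$sensor == "steps"; a <- df$sensor == "app"
  raw_stream(df$patient_id[1],
             gps = data.frame(time = t[g],
                              lat = df[["payload.lat"]][g],
                              lon = df[["payload.lon"]][g]),
             steps = data.frame(time = t[s],
                                steps = df[["payload.steps"]][s]),
             app = data.frame(time = t[a]))
}

#' Write ground truth as CSV files
#'
#' Writes `<prefix>_labels.csv` (day, profile, change_point),
#' `<prefix>_events.csv` (day, type) and `<prefix>_missing.csv`.
#'
#' @param truth the `truth` element of [generate_patient()].
#' @param prefix path prefix.
#' @export
write_truth_csv <- function(truth, prefix) {
  d <- length(truth$labels)
  utils::write.csv(
    data.frame(day = seq_len(d) - 1L, profile = truth$labels,
               change_point = (seq_len(d) - 1L) %in% truth$change_points),
    paste0(prefix, "_labels.csv"), row.names = FALSE)
  utils::write.csv(truth$events, paste0(prefix, "_events.csv"),
                   row.names = FALSE)
  utils::write.csv(
    cbind(data.frame(day = seq_len(d) - 1L), as.data.frame(truth$missing)),
    paste0(prefix, "_missing.csv"), row.names = FALSE)
  invisible(prefix)
}
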