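# Raw-stream preprocessing: home inference, the four binning operations, and
# daily feature assembly.

test_that("home inference returns the densest night cluster", {
  day0 <- utc("2020-01-01")
  # all night fixes at one coordinate -> that coordinate
  fixes <- data.frame(time = day0 + c(3600, 7200, 10800),
                      lat = 40.5, lon = -3.6)
  h <- infer_home(fixes)
  expect_equal(h$lat, 40.5)
  expect_equal(h$lon, -3.6)
  expect_gte(h$support_nights, 1)

  # no fixes between 00:00 and 06:00 -> error
  noon <- data.frame(time = day0 + 12 * 3600, lat = 40, lon = -3)
  expect_error(infer_home(noon), "home undeterminable")

  # two night clusters with 70%/30% dwell -> majority centroid.
  # Cluster A: 00:00-04:12 (70%), cluster B: 04:12-06:00 (30%).
  tA <- day0 + seq(0, 4.2 * 3600, by = 300)
  tB <- day0 + seq(4.2 * 3600 + 300, 6 * 3600 - 1, by = 300)
  fixes2 <- rbind(data.frame(time = tA, lat = 40.40, lon = -3.70),
                  data.frame(time = tB, lat = 40.45, lon = -3.65))
  h2 <- infer_home(fixes2)
  expect_equal(h2$lat, 40.40, tolerance = 1e-6)
  expect_equal(h2$lon, -3.70, tolerance = 1e-6)
})

test_that("bin_distance sums segment distances into midpoint bins", {
  day0 <- utc("2020-01-01")
  # stationary patient: all observed bins zero
  st <- full_day_gps(day0, 40.4, -3.7)
  bd <- bin_distance(st)
  expect_true(all(bd$mask))
  expect_true(all(bd$value == 0))

  # no fixes: all missing
  bd0 <- bin_distance(st[0, ])
  expect_true(all(!bd0$mask))
  expect_true(all(is.na(bd0$value)))

  # two fixes 0.01 deg of longitude apart on the equator, both in bin 2
  fixes <- data.frame(time = day0 + c(3600, 3900), lat = 0,
                      lon = c(10, 10.01))
  bd2 <- bin_distance(fixes)
  expected_m <- slc_distance_m(0, 10, 0, 10.01)  # independent oracle
  expect_equal(expected_m, 1111.95, tolerance = 1e-4)
  expect_equal(bd2$value[3], log1p(expected_m), tolerance = 1e-9)
  expect_identical(which(bd2$mask), 3L)
})

test_that("bin_home flags bins within the home radius", {
  day0 <- utc("2020-01-01")
  home <- structure(list(lat = 40.4, lon = -3.7, support_nights = 5L),
                    class = "home_location")
  st <- full_day_gps(day0, 40.4, -3.7)
  bh <- bin_home(st, home)
  expect_true(all(bh$mask) && all(bh$value == 1))

  far <- full_day_gps(day0, 40.49, -3.7)   # ~10 km north
  bf <- bin_home(far, home)
  expect_true(all(bf$mask) && all(bf$value == 0))

  # home fixes only in bins 0-15 (00:00-08:00), away fixes in bins 16-47
  mixed <- full_day_gps(day0, 40.49, -3.7)
  early <- as.numeric(mixed$time - day0, units = "secs") < 8 * 3600
  mixed$lat[early] <- 40.4
  bm <- bin_home(mixed, home)
  expect_true(all(bm$value[1:16] == 1))
  expect_true(all(bm$value[17:48] == 0))
  expect_true(all(bm$mask))
})

test_that("bin_steps uses log1p totals and the heartbeat rule", {
  day0 <- utc("2020-01-01")
  ev <- data.frame(time = day0 + 20 * 1800 + 60, steps = 1000)
  bs <- bin_steps(ev)
  expect_equal(bs$value[21], log1p(1000))
  expect_equal(log1p(1000), 6.9088, tolerance = 1e-4)
  expect_true(all(bs$value[-21] == 0))
  expect_true(all(bs$mask))             # heartbeat exists -> day observed

  # zero-count heartbeat: true zeros, observed
  hb <- data.frame(time = day0 + 3600, steps = 0)
  b0 <- bin_steps(hb)
  expect_true(all(b0$value == 0) && all(b0$mask))

  # no record at all: fully missing
  bm <- bin_steps(hb[0, ])
  expect_true(all(!bm$mask))

  expect_error(bin_steps(data.frame(time = day0, steps = -5)), ">= 0")
})

test_that("bin_app_usage marks exactly the bins with events", {
  day0 <- utc("2020-01-01")
  ev <- data.frame(time = day0 + c(10, 30) * 1800 + 900)
  ba <- bin_app_usage(ev)
  expect_identical(which(ba$value == 1), c(11L, 31L))
  expect_true(all(ba$mask))
  all_bins <- data.frame(time = day0 + (0:47) * 1800 + 1)
  expect_true(all(bin_app_usage(all_bins)$value == 1))
  none <- bin_app_usage(ev[0, , drop = FALSE])
  expect_true(all(!none$mask))
})

test_that("build_daily_features assembles days and preserves missing ones", {
  cfg <- scenario_config(days_per_patient = 5)
  pat <- generate_patient(cfg, 31)
  f <- build_daily_features(pat$stream)
  expect_s3_class(f, "daily_features")
  expect_identical(f$days, 0:4)
  for (v in c("distance", "steps", "home", "app"))
    expect_identical(ncol(f[[v]]), 48L)
  # fully observed day: all four masks true everywhere
  expect_true(all(vapply(f$mask, function(m) all(m[1, ]), logical(1))))

  # empty stream -> empty matrix
  f0 <- build_daily_features(generate_patient(
    scenario_config(days_per_patient = 0), 1)$stream)
  expect_identical(length(f0$days), 0L)

  # a totally missing middle day survives as an all-missing row
  drop_day <- function(df, origin, day) {
    di <- floor(as.numeric(difftime(df$time, origin, units = "days")))
    df[di != day, , drop = FALSE]
  }
  s <- pat$stream
  s2 <- raw_stream(s$patient_id, drop_day(s$gps, s$origin, 2),
                   drop_day(s$steps, s$origin, 2),
                   drop_day(s$app, s$origin, 2), origin = s$origin)
  f2 <- build_daily_features(s2)
  expect_identical(length(f2$days), 5L)
  expect_true(all(vapply(f2$mask, function(m) !any(m[3, ]), logical(1))))
  expect_identical(totally_missing_days(f2), c(F, F, T, F, F))

  # no night fixes at all -> home fully missing, everything else proceeds
  day0 <- utc("2020-01-01")
  daytime <- data.frame(time = day0 + seq(8 * 3600, 20 * 3600, by = 300),
                        lat = 40.4, lon = -3.7)
  sd <- raw_stream("x", daytime,
                   steps = data.frame(time = day0 + 9 * 3600, steps = 100),
                   app = data.frame(time = day0 + 10 * 3600))
  fd <- build_daily_features(sd)
  expect_true(all(!fd$mask$home))
  expect_true(any(fd$mask$distance))
})

test_that("log1p binning is monotone under scaling of raw magnitudes", {
  day0 <- utc("2020-01-01")
  set.seed(8)
  n <- 100
  fixes <- data.frame(time = day0 + sort(sample(0:86399, n)),
                      lat = 40.4 + cumsum(rnorm(n, 0, 1e-4)),
                      lon = -3.7 + cumsum(rnorm(n, 0, 1e-4)))
  b1 <- bin_distance(fixes)
  scaled <- fixes
  scaled$lat <- 40.4 + (fixes$lat - 40.4) * 3
  scaled$lon <- -3.7 + (fixes$lon + 3.7) * 3
  b3 <- bin_distance(scaled)
  obs <- b1$mask
  expect_true(all(b3$value[obs] >= b1$value[obs]))

  ev <- data.frame(time = day0 + sort(sample(0:86399, 20)),
                   steps = rpois(20, 200))
  s1 <- bin_steps(ev)
  ev2 <- ev; ev2$steps <- ev$steps * 5
  s5 <- bin_steps(ev2)
  expect_true(all(s5$value >= s1$value))
})

test_that("generated emissions are recovered through preprocessing", {
  # cross-module: per-profile at-home and app frequencies match the profile
  # parameters; activity magnitudes preserve the configured ordering
  cfg <- scenario_config(days_per_patient = 120, rng_seed = 5,
                         p_background_event = 0)
  pat <- generate_patient(cfg, 99)
  f <- build_daily_features(pat$stream)
  lab <- pat$truth$labels
  day_bins <- 15:48                      # bins 14..47 are daytime
  profs <- default_profiles()
  for (k in 1:2) {
    hk <- f$home[lab == k, day_bins][f$mask$home[lab == k, day_bins]]
    ak <- f$app[lab == k, day_bins][f$mask$app[lab == k, day_bins]]
    expect_lt(abs(mean(hk) - profs[[k]]$p_home_day),
              3 * sqrt(0.25 / length(hk)) + 0.02)
    expect_lt(abs(mean(ak) - profs[[k]]$p_app_day),
              3 * sqrt(0.25 / length(ak)) + 0.02)
  }
  expect_gt(mean(f$distance[lab == 1, day_bins]),
            mean(f$distance[lab == 2, day_bins]))
  expect_gt(mean(f$steps[lab == 1, day_bins]),
            mean(f$steps[lab == 2, day_bins]))
})
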