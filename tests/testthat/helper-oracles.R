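# Independent oracles and small fixture builders shared across tests.

# One-hot profile matrix from a label sequence.
one_hot_mat <- function(labels, K) {
  m <- matrix(0, length(labels), K)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

# Independent great-circle oracle: spherical law of cosines, R = 6371 km.
# Deliberately a different formula than the implementation's haversine.
slc_distance_m <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  6371000 * acos(pmin(1, sin(lat1 * to_rad) * sin(lat2 * to_rad) +
                        cos(lat1 * to_rad) * cos(lat2 * to_rad) *
                        cos((lon2 - lon1) * to_rad)))
}

# Exhaustive-segmentation oracle for the run-length posterior at time T:
# enumerate all 2^(T-1) segmentations, score each with the constant-hazard
# prior and Dirichlet-categorical marginal likelihoods, and tally the
# posterior of the final run length.
oracle_runlength <- function(labels, K, alpha, h) {
  T <- length(labels)
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  seg_marg <- function(lbl) {
    n <- tabulate(lbl, K)
    lgamma(sum(alpha)) - sum(lgamma(alpha)) +
      sum(lgamma(alpha + n)) - lgamma(sum(alpha) + sum(n))
  }
  rl <- numeric(T)
  for (m in 0:(2^(T - 1) - 1)) {
    cps <- if (T > 1) which(bitwAnd(m, 2^(0:(T - 2))) > 0) else integer(0)
    bounds <- c(0, cps, T)
    lp <- length(cps) * log(h) + (T - 1 - length(cps)) * log(1 - h)
    for (s in seq_len(length(bounds) - 1))
      lp <- lp + seg_marg(labels[(bounds[s] + 1):bounds[s + 1]])
    r_T <- T - (if (length(cps)) max(cps) else 0) - 1
    rl[r_T + 1] <- rl[r_T + 1] + exp(lp)
  }
  rl / sum(rl)
}

# Well-separated K-profile emission parameters in model space (96 continuous
# + 96 binary dims). Mean gaps >= 1.5 with sd sigma (default 10x separation).
separated_emissions <- function(K = 3, sigma = 0.15) {
  mu <- matrix(rep(seq(0, 1.5 * (K - 1), length.out = K), 96), K, 96)
  mu <- mu + outer(seq_len(K), seq_len(96),
                   function(k, j) 0.3 * sin(j / 8 + k))
  p <- matrix(0.15, K, 96)
  for (k in seq_len(K)) p[k, (seq_len(96) + k) %% K == 0] <- 0.85
  list(mu = mu, sigma = matrix(sigma, K, 96), p = p)
}

# Fully observed single-day GPS track: one fix per 5 minutes at given coords.
full_day_gps <- function(day0, lat, lon) {
  n <- 288
  data.frame(time = day0 + (seq_len(n) - 1) * 300,
             lat = rep_len(lat, n), lon = rep_len(lon, n))
}

utc <- function(s) as.POSIXct(s, tz = "UTC")

# Change-probability series from a label sequence via the expected-mode
# change-point recursion (used by evaluation-stage experiments).
series_from_labels <- function(labels, K = 2, h = 1 / 60, w = 7) {
  rl <- run_bocpd(one_hot_mat(labels, K),
                  bocpd_config(hazard = h, n_samples = 0))
  change_window_probability(rl, w)
}
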