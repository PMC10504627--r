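# Bayesian online change-point detection over the daily profile sequence.
#
# A latent run length r_t counts the exact number of days since the last
# change point (r_t = 0: the pattern started today). Each behavioral pattern
# draws daily profiles from an unknown categorical distribution with a
# Dirichlet prior, so the per-run-length posterior predictive is
# Dirichlet-categorical. With a constant per-day hazard h the filtering
# recursion is
#   P(r_t = r+1) growth mass  = P(r_{t-1} = r) (1-h) pred_r(x_t)
#   P(r_t = 0)  change mass   = sum_r P(r_{t-1} = r) h  pred_prior(x_t)
# followed by renormalization, where pred_r conditions on the r+1
# observations already attributed to that run and pred_prior on none (the
# day that starts a new pattern is predicted under the prior). On a totally
# missing day every predictive is 1 (the missing observation is marginalized
# out), so the row evolves by hazard mixing alone and no run-length
# hypothesis changes its sufficient statistics.

#' Configuration for the change-point detector
#'
#' @param hazard constant per-day prior probability that a new behavioral
#'   pattern starts. Default 1/60 (expected pattern length about two months).
#' @param alpha Dirichlet concentration: scalar (replicated over profiles) or
#'   K-vector of positive reals. Default 1 (uniform).
#' @param n_samples number of sampled daily-profile paths averaged at the
#'   run-length-posterior level; 0 uses the expected profile vector instead
#'   (deterministic). Default 30.
#' @param seed RNG seed for the sampled mode.
#' @param run_length_cap run lengths above the cap are truncated and the row
#'   renormalized. Default 365.
#' @return a `bocpd_config` list.
#' @export
bocpd_config <- function(hazard = 1 / 60, alpha = 1, n_samples = 30,
                         seed = 1, run_length_cap = 365) {
  if (!is.numeric(hazard) || hazard <= 0 || hazard >= 1)
    stop_invalid("hazard must lie in (0, 1)")
  if (any(alpha <= 0)) stop_invalid("alpha must be positive")
  if (n_samples < 0) stop_invalid("n_samples must be >= 0")
  if (run_length_cap < 1) stop_invalid("run_length_cap must be >= 1")
  structure(list(hazard = hazard, alpha = alpha,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 run_length_cap = as.integer(run_length_cap)),
            class = "bocpd_config")
}

#' Dirichlet-categorical posterior predictive
#'
#' Probability of the next day's profile given the counts already attributed
#' to a run: `(alpha_k + count_k) / (sum(alpha) + sum(count))`. When the
#' observation is a probability vector over profiles (expected mode), returns
#' the simplex-weighted mixture of the per-label predictives.
#'
#' @param counts K-vector of (possibly fractional) profile counts in the run.
#' @param alpha K-vector of Dirichlet concentrations.
#' @param observation integer profile label in 1..K, or a K-simplex vector.
#' @return predictive probability.
#' @export
predictive_prob <- function(counts, alpha, observation) {
  if (length(alpha) == 1) alpha <- rep(alpha, length(counts))
  pk <- (alpha + counts) / (sum(alpha) + sum(counts))
  if (length(observation) == 1 && observation == as.integer(observation) &&
      observation >= 1) {
    pk[as.integer(observation)]
  } else {
    check_simplex(observation, "observation")
    sum(observation * pk)
  }
}

# One filtering step. state: list(w = weights over r = 0..R-1,
# counts = R x K matrix of per-run-length profile counts).
# obs: K-vector (one-hot or simplex) or NULL for a totally missing day.
bocpd_step_state <- function(state, obs, hazard, alpha, cap) {
  w <- state$w
  counts <- state$counts
  k <- ncol(counts)
  r_act <- length(w)
  if (is.null(obs)) {                 # missing day: hazard mixing only
    new_w <- c(hazard * sum(w), (1 - hazard) * w)
    new_counts <- rbind(rep(0, k), counts)
  } else {
    tot <- rowSums(counts) + sum(alpha)
    pred <- as.vector((counts %*% obs) + sum(alpha * obs)) / tot
    pred0 <- sum(alpha * obs) / sum(alpha)
    new_w <- c(pred0 * hazard * sum(w), (1 - hazard) * w * pred)
    new_counts <- rbind(obs, sweep(counts, 2, -obs))
  }
  if (length(new_w) > cap + 1) {      # truncate run lengths beyond the cap
    new_w <- new_w[seq_len(cap + 1)]
    new_counts <- new_counts[seq_len(cap + 1), , drop = FALSE]
  }
  list(w = new_w / sum(new_w), counts = new_counts)
}

#' One day of the run-length recursion
#'
#' Advances the run-length posterior by one observation (or by a totally
#' missing day). Exposed mainly for testing; [run_bocpd()] drives it.
#'
#' @param prev_row numeric weights over run lengths 0..R-1 (simplex).
#' @param prev_counts R x K matrix of profile counts per run-length
#'   hypothesis (row r+1 holds the counts of the run of length r).
#' @param observation K-vector (one-hot label or simplex), or `NULL` for a
#'   totally missing day.
#' @param config a [bocpd_config()].
#' @return list with the new `w` (simplex over run lengths 0..R) and
#'   `counts`.
#' @export
bocpd_step <- function(prev_row, prev_counts, observation, config) {
  check_simplex(prev_row, "prev_row", tol = 1e-8)
  alpha <- config$alpha
  if (length(alpha) == 1) alpha <- rep(alpha, ncol(prev_counts))
  bocpd_step_state(list(w = prev_row, counts = prev_counts), observation,
                   config$hazard, alpha, config$run_length_cap)
}

# Full pass over a sequence of observations (list of K-vectors or NULL).
bocpd_pass <- function(obs_list, hazard, alpha, cap) {
  t_n <- length(obs_list)
  rl <- matrix(0, t_n, min(t_n, cap + 1))
  state <- list(w = 1, counts = matrix(0, 1, length(alpha)))
  for (t in seq_len(t_n)) {
    if (t == 1) {
      # first day: the run necessarily started today
      obs <- obs_list[[1]]
      state <- list(w = 1,
                    counts = matrix(if (is.null(obs)) 0 else obs, 1,
                                    length(alpha), byrow = TRUE))
    } else {
      state <- bocpd_step_state(state, obs_list[[t]], hazard, alpha, cap)
    }
    rl[t, seq_along(state$w)] <- state$w
  }
  rl
}

#' Run-length posterior over a daily profile sequence
#'
#' Runs the hierarchical Bayesian online change-point recursion over the
#' per-day profile posterior. With `n_samples > 0`, profile uncertainty is
#' propagated by sampling: `n_samples` label paths are drawn from the per-day
#' posteriors and the resulting run-length posteriors averaged. With
#' `n_samples = 0` the expected profile vector is used directly
#' (deterministic, fractional counts).
#'
#' @param posterior a `profile_posterior` (from [profile_posterior()] or
#'   [select_profiles()]), or a row-stochastic days x K matrix.
#' @param config a [bocpd_config()].
#' @param missing optional logical vector marking totally missing days; taken
#'   from the `profile_posterior` if present.
#' @return a `run_length_posterior`: list with `prob` (days x (max run + 1)
#'   matrix, rows on the simplex, `prob[t, r + 1] = P(r_t = r)`), `missing`,
#'   `days`, `config`.
#' @export
run_bocpd <- function(posterior, config = bocpd_config(), missing = NULL) {
  if (inherits(posterior, "profile_posterior")) {
    prob <- posterior$prob
    if (is.null(missing)) missing <- posterior$missing
    days <- posterior$days
    patient_id <- posterior$patient_id
  } else {
    prob <- as.matrix(posterior)
    days <- seq_len(nrow(prob)) - 1L
    patient_id <- NA
  }
  t_n <- nrow(prob)
  if (is.null(missing)) missing <- rep(FALSE, t_n)
  if (t_n == 0) {
    return(structure(list(prob = matrix(0, 0, 0), missing = logical(0),
                          days = integer(0), config = config),
                     class = "run_length_posterior"))
  }
  k <- ncol(prob)
  bad <- !missing & abs(rowSums(prob) - 1) > 1e-6
  if (any(bad)) stop_invalid("profile posterior rows must lie on the simplex")
  alpha <- config$alpha
  if (length(alpha) == 1) alpha <- rep(alpha, k)
  cap <- config$run_length_cap
  one_hot <- function(lbl) { v <- numeric(k); v[lbl] <- 1; v }
  if (config$n_samples == 0) {
    obs <- lapply(seq_len(t_n), function(t)
      if (missing[t]) NULL else prob[t, ])
    rl <- bocpd_pass(obs, config$hazard, alpha, cap)
  } else {
    rl <- 0
    for (s in seq_len(config$n_samples)) {
      set.seed(derive_seed(config$seed, s))
      obs <- lapply(seq_len(t_n), function(t) {
        if (missing[t]) return(NULL)
        one_hot(sample.int(k, 1, prob = prob[t, ]))
      })
      rl <- rl + bocpd_pass(obs, config$hazard, alpha, cap)
    }
    rl <- rl / config$n_samples
  }
  structure(list(prob = rl, missing = missing, days = days,
                 patient_id = patient_id, config = config),
            class = "run_length_posterior")
}

#' @export
print.run_length_posterior <- function(x, ...) {
  cat(sprintf("<run_length_posterior> %d day(s), run lengths 0..%d\n",
              nrow(x$prob), ncol(x$prob) - 1))
  invisible(x)
}

#' Cumulative probability of a recent change
#'
#' The probability, for each day, that a change point occurred within the
#' previous `w` days: a change in the last `w` days is exactly the event
#' that the current run length is below `w`, so the value at day `d` is
#' `sum_{r < w} P(r_d = r)`. Days `d < w` saturate at 1 (the run necessarily
#' started within the window).
#'
#' @param rlp a `run_length_posterior` from [run_bocpd()].
#' @param w window length in days (default 7).
#' @return numeric vector in `[0, 1]`, one value per day, with attribute
#'   `"window"`.
#' @export
change_window_probability <- function(rlp, w = 7) {
  if (w <= 0) stop_invalid("window w must be a positive number of days")
  idx <- seq_len(min(w, ncol(rlp$prob)))
  out <- rowSums(rlp$prob[, idx, drop = FALSE])
  out <- pmin(pmax(out, 0), 1)
  attr(out, "window") <- w
  out
}

#' Write a run-length posterior as tidy CSV
#'
#' Columns: `patient_id, day, run_length, probability`; zero-probability
#' cells are omitted.
#'
#' @param rlp a `run_length_posterior`.
#' @param path output CSV path.
#' @export
write_runlength_csv <- function(rlp, path) {
  t_n <- nrow(rlp$prob); rmax <- ncol(rlp$prob)
  df <- data.frame(
    patient_id = rlp$patient_id,
    day = rep(rlp$days, rmax),
    run_length = rep(0:(rmax - 1L), each = t_n),
    probability = as.vector(rlp$prob))
  df <- df[df$probability > 0, ]
  utils::write.csv(df[order(df$day, df$run_length), ], path,
                   row.names = FALSE)
  invisible(path)
}
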