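# Per-patient daily profiling with a heterogeneous mixture model: each
# component models the 96 continuous bins (log-distance, log-steps) with
# independent Gaussians and the 96 binary bins (home, app) with independent
# Bernoullis. Dimension independence given the component makes marginalizing
# partially missing bins exact: unobserved dimensions simply drop out of the
# per-component likelihood product.

#' Construct a heterogeneous mixture model
#'
#' @param weights component weights on the simplex (length K, K <= 10).
#' @param mu,sigma2 K x 96 Gaussian means and variances for the continuous
#'   bins (48 distance then 48 steps, log1p scale).
#' @param p K x 96 Bernoulli probabilities for the binary bins (48 home then
#'   48 app).
#' @param var_floor,p_eps numerical guards applied at construction: variances
#'   are floored and Bernoulli probabilities clipped to `[p_eps, 1 - p_eps]`.
#' @return an object of class `hetmix`.
#' @export
hetmix_model <- function(weights, mu, sigma2, p,
                         var_floor = 1e-4, p_eps = 1e-3) {
  k <- length(weights)
  if (k < 1 || k > 10) stop_invalid("number of components must be in 1..10")
  check_simplex(weights, "weights")
  if (!all(dim(mu) == c(k, ncol(mu))) || any(dim(sigma2) != dim(mu)))
    stop_invalid("mu and sigma2 must be K x D_cont matrices")
  sigma2 <- pmax(sigma2, var_floor)
  p <- pmin(pmax(p, p_eps), 1 - p_eps)
  structure(list(K = k, weights = as.numeric(weights), mu = mu,
                 sigma2 = sigma2, p = p,
                 var_floor = var_floor, p_eps = p_eps),
            class = "hetmix")
}

#' @export
print.hetmix <- function(x, ...) {
  cat(sprintf("<hetmix> %d component(s), %d continuous + %d binary dims\n",
              x$K, ncol(x$mu), ncol(x$p)))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

# Matrix of per-day, per-component log-likelihoods with exact marginalization
# of unobserved dimensions. xc: D x 96 continuous, xb: D x 96 binary,
# mc/mb logical masks (TRUE observed). Returns D x K.
hetmix_loglik_matrix <- function(model, xc, xb, mc, mb) {
  d <- nrow(xc); k <- model$K
  xc0 <- ifelse(mc, xc, 0)
  xb0 <- ifelse(mb, xb, 0)
  ll <- matrix(0, d, k)
  for (j in seq_len(k)) {
    mu <- model$mu[j, ]; s2 <- model$sigma2[j, ]
    # Gaussian term per observed continuous bin
    g <- -0.5 * (log(2 * pi * matrix(s2, d, length(s2), byrow = TRUE)) +
                   sweep(xc0, 2, mu)^2 /
                   matrix(s2, d, length(s2), byrow = TRUE))
    g[!mc] <- 0
    pj <- model$p[j, ]
    lb <- xb0 * matrix(log(pj), d, length(pj), byrow = TRUE) +
      (1 - xb0) * matrix(log1p(-pj), d, length(pj), byrow = TRUE)
    lb[!mb] <- 0
    ll[, j] <- rowSums(g) + rowSums(lb)
  }
  ll
}

#' Per-component log-likelihood of a single day
#'
#' Computes `log p(x_d | component k)` for each component, marginalizing
#' unobserved dimensions exactly (they drop out of the product). A totally
#' missing day therefore has log-likelihood 0 for every component.
#'
#' @param model a [hetmix_model()].
#' @param day_features numeric vector of length 192 in model layout
#'   (48 distance, 48 steps, 48 home, 48 app).
#' @param day_mask logical vector of length 192, `TRUE` where observed.
#' @return numeric vector of length K.
#' @export
day_loglik <- function(model, day_features, day_mask) {
  nc <- ncol(model$mu); nb <- ncol(model$p)
  if (length(day_features) != nc + nb || length(day_mask) != nc + nb)
    stop_invalid("day vector must have length %d", nc + nb)
  xc <- matrix(day_features[seq_len(nc)], 1)
  xb <- matrix(day_features[nc + seq_len(nb)], 1)
  mc <- matrix(day_mask[seq_len(nc)], 1)
  mb <- matrix(day_mask[nc + seq_len(nb)], 1)
  drop(hetmix_loglik_matrix(model, xc, xb, mc, mb))
}

# Responsibilities and observed-data log-likelihood for flattened features.
hetmix_estep <- function(model, fl) {
  ll <- hetmix_loglik_matrix(model, fl$xc, fl$xb, fl$mc, fl$mb)
  lw <- sweep(ll, 2, log(model$weights), `+`)
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  tot <- rowSums(w)
  list(resp = w / tot, loglik = sum(mx + log(tot)))
}

#' Per-day profile posterior
#'
#' Responsibility of each profile for each day. Rows lie on the simplex;
#' rows of totally missing days equal the mixture weights exactly.
#'
#' @param model a [hetmix_model()].
#' @param features a [daily_features()] object.
#' @param min_obs_frac days observed below this fraction are treated as
#'   totally missing (posterior row = mixture weights).
#' @return a `profile_posterior`: list with `prob` (days x K row-stochastic
#'   matrix), `missing` (logical, totally missing days), `days`.
#' @export
profile_posterior <- function(model, features, min_obs_frac = 0.1) {
  miss <- totally_missing_days(features, min_obs_frac)
  fl <- flatten_features(features)
  # blank out sub-threshold days entirely so their rows equal the weights
  fl$mc[miss, ] <- FALSE
  fl$mb[miss, ] <- FALSE
  es <- hetmix_estep(model, fl)
  prob <- es$resp
  if (any(miss))
    prob[miss, ] <- matrix(model$weights, sum(miss), model$K, byrow = TRUE)
  structure(list(prob = prob, missing = miss, days = features$days,
                 patient_id = features$patient_id),
            class = "profile_posterior")
}

# kmeans++-style seeding on mean-imputed, z-scored observed dims.
seed_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
    for (j in 2:k) {
      pr <- d2 / sum(d2)
      if (!all(is.finite(pr)) || sum(d2) == 0) pr <- rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = pr)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j], ])^2))
    }
  }
  centers
}

hetmix_mstep <- function(resp, fl, var_floor, p_eps, old = NULL) {
  k <- ncol(resp)
  nc <- ncol(fl$xc); nb <- ncol(fl$xb)
  xc0 <- ifelse(fl$mc, fl$xc, 0)
  xb0 <- ifelse(fl$mb, fl$xb, 0)
  weights <- colMeans(resp)
  weights <- weights / sum(weights)
  mu <- matrix(0, k, nc); s2 <- matrix(var_floor, k, nc)
  p <- matrix(0.5, k, nb)
  for (j in seq_len(k)) {
    wc <- resp[, j] * fl$mc                    # D x nc effective weights
    denc <- colSums(wc)
    okc <- denc > 0
    mu[j, okc] <- colSums(wc * xc0)[okc] / denc[okc]
    s2[j, okc] <- colSums(wc * sweep(xc0, 2, mu[j, ])^2)[okc] / denc[okc]
    if (!is.null(old)) {
      mu[j, !okc] <- old$mu[j, !okc]
      s2[j, !okc] <- old$sigma2[j, !okc]
    }
    wb <- resp[, j] * fl$mb
    denb <- colSums(wb)
    okb <- denb > 0
    p[j, okb] <- colSums(wb * xb0)[okb] / denb[okb]
    if (!is.null(old)) p[j, !okb] <- old$p[j, !okb]
  }
  hetmix_model(weights, mu, pmax(s2, var_floor),
               pmin(pmax(p, p_eps), 1 - p_eps),
               var_floor = var_floor, p_eps = p_eps)
}

em_single <- function(fl, k, tol, max_iter, var_floor, p_eps) {
  d <- nrow(fl$xc)
  # init: impute by column means, z-score, kmeans++ seeds, hard assign
  x <- cbind(ifelse(fl$mc, fl$xc, NA), ifelse(fl$mb, fl$xb, NA))
  cm <- colMeans(x, na.rm = TRUE); cm[is.na(cm)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- cm[j]
  cs <- apply(x, 2, stats::sd); cs[cs < 1e-8] <- 1
  z <- sweep(sweep(x, 2, colMeans(x)), 2, cs, `/`)
  ctr <- seed_centers(z, k)
  assign <- apply(z, 1, function(r)
    which.min(colSums((t(z[ctr, , drop = FALSE]) - r)^2)))
  resp <- matrix(1e-3, d, k)
  resp[cbind(seq_len(d), assign)] <- 1
  resp <- resp / rowSums(resp)
  model <- hetmix_mstep(resp, fl, var_floor, p_eps)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    es <- hetmix_estep(model, fl)
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) <= tol * (abs(ll_old) + 1e-10)) break
    ll_old <- es$loglik
    model <- hetmix_mstep(es$resp, fl, var_floor, p_eps, old = model)
  }
  list(model = model, loglik = trace[length(trace)], trace = trace)
}

#' Fit a heterogeneous mixture model by EM
#'
#' Expectation-maximization over the observed-data likelihood with exact
#' marginalization of missing bins. Best of `n_restarts` seeded restarts is
#' returned; the observed-data log-likelihood is non-decreasing across
#' iterations (stored in `attr(, "loglik_trace")`).
#'
#' @param features a [daily_features()] object.
#' @param K number of components (1..10).
#' @param n_restarts random restarts (default 5).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param seed RNG seed (restarts are seeded deterministically from it).
#' @param var_floor,p_eps degeneracy guards.
#' @param min_obs_frac threshold below which a day is treated as totally
#'   missing and excluded from fitting.
#' @return a fitted [hetmix_model()] with attributes `loglik`,
#'   `loglik_trace` and `n_days_used`.
#' @export
em_fit <- function(features, K, n_restarts = 5, tol = 1e-5, max_iter = 200,
                   seed = 1, var_floor = 1e-4, p_eps = 1e-3,
                   min_obs_frac = 0.1) {
  if (K < 1 || K > 10) stop_invalid("K must be in 1..10")
  miss <- totally_missing_days(features, min_obs_frac)
  if (sum(!miss) < K)
    stop_invalid("insufficient data: %d usable day(s) for K=%d components",
                 sum(!miss), K)
  fl <- flatten_features(features)
  fl <- list(xc = fl$xc[!miss, , drop = FALSE],
             xb = fl$xb[!miss, , drop = FALSE],
             mc = fl$mc[!miss, , drop = FALSE],
             mb = fl$mb[!miss, , drop = FALSE])
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    fit <- em_single(fl, K, tol, max_iter, var_floor, p_eps)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  model <- best$model
  attr(model, "loglik") <- best$loglik
  attr(model, "loglik_trace") <- best$trace
  attr(model, "n_days_used") <- sum(!miss)
  model
}

#' Bayesian information criterion of a fitted model
#'
#' `BIC = -2 loglik + n_params log(n_days_used)`; lower is better. Parameters
#' counted: K-1 free weights, K x 96 means, K x 96 variances, K x 96
#' Bernoulli probabilities.
#'
#' @param model a fitted [hetmix_model()] (from [em_fit()]).
#' @param features the features it was fitted on (used if the model lacks a
#'   stored log-likelihood).
#' @param min_obs_frac totally-missing threshold, must match the fit.
#' @return BIC value.
#' @export
bic_score <- function(model, features, min_obs_frac = 0.1) {
  miss <- totally_missing_days(features, min_obs_frac)
  n <- sum(!miss)
  ll <- attr(model, "loglik")
  if (is.null(ll)) {
    fl <- flatten_features(features)
    fl <- list(xc = fl$xc[!miss, , drop = FALSE],
               xb = fl$xb[!miss, , drop = FALSE],
               mc = fl$mc[!miss, , drop = FALSE],
               mb = fl$mb[!miss, , drop = FALSE])
    ll <- hetmix_estep(model, fl)$loglik
  }
  n_params <- (model$K - 1) + model$K * (2 * ncol(model$mu) + ncol(model$p))
  -2 * ll + n_params * log(n)
}

#' Select the number of daily profiles by BIC
#'
#' Fits mixtures with K = 1..`K_max` components and returns the
#' BIC-minimizing model together with its per-day profile posterior.
#'
#' @inheritParams em_fit
#' @param K_max maximum number of profiles (1..10).
#' @param ... passed to [em_fit()].
#' @return list with `model`, `posterior` (a `profile_posterior`), `K`, and
#'   the per-K `bic` vector.
#' @export
select_profiles <- function(features, K_max = 10, seed = 1,
                            min_obs_frac = 0.1, ...) {
  if (K_max < 1 || K_max > 10) stop_invalid("K_max must be in 1..10")
  usable <- sum(!totally_missing_days(features, min_obs_frac))
  ks <- seq_len(min(K_max, usable))
  fits <- lapply(ks, function(k)
    em_fit(features, k, seed = derive_seed(seed, k),
           min_obs_frac = min_obs_frac, ...))
  bic <- vapply(seq_along(ks), function(i)
    bic_score(fits[[i]], features, min_obs_frac), numeric(1))
  best <- which.min(bic)
  model <- fits[[best]]
  list(model = model,
       posterior = profile_posterior(model, features, min_obs_frac),
       K = ks[best], bic = stats::setNames(bic, paste0("K", ks)))
}

#' Serialize a fitted model to JSON
#'
#' @param model a [hetmix_model()].
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, weights = model$weights, mu = model$mu,
         sigma2 = model$sigma2, p = model$p),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write a profile posterior as tidy CSV
#'
#' Columns: `patient_id, day, profile, probability`.
#'
#' @param posterior a `profile_posterior`.
#' @param path output CSV path.
#' @export
write_posterior_csv <- function(posterior, path) {
  k <- ncol(posterior$prob)
  df <- data.frame(
    patient_id = posterior$patient_id,
    day = rep(posterior$days, k),
    profile = rep(seq_len(k), each = length(posterior$days)),
    probability = as.vector(posterior$prob))
  utils::write.csv(df[order(df$day, df$profile), ], path, row.names = FALSE)
  invisible(path)
}
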