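# Heterogeneous mixture profiling: marginalized likelihoods, EM, BIC.

test_that("day_loglik marginalizes missing dimensions exactly", {
  em <- separated_emissions(2)
  model <- hetmix_model(c(0.5, 0.5), em$mu, em$sigma^2, em$p)

  # all dims missing -> zero log-likelihood for every component
  x <- rep(0, 192)
  expect_identical(day_loglik(model, x, rep(FALSE, 192)), c(0, 0))

  # partially observed: equals the hand-built sum over observed dims only
  mask <- rep(FALSE, 192)
  mask[c(1, 50, 97, 150)] <- TRUE
  x[c(1, 50)] <- c(1.2, -0.3); x[c(97, 150)] <- c(1, 0)
  manual <- vapply(1:2, function(k) {
    dnorm(1.2, em$mu[k, 1], 0.15, log = TRUE) +
      dnorm(-0.3, em$mu[k, 50], 0.15, log = TRUE) +
      dbinom(1, 1, model$p[k, 1], log = TRUE) +
      dbinom(0, 1, model$p[k, 54], log = TRUE)
  }, numeric(1))
  expect_equal(day_loglik(model, x, mask), manual, tolerance = 1e-12)
})

test_that("two-component posterior matches Bayes' rule by hand", {
  # one informative Gaussian dim (mu 0 vs 3, sd 1), one Bernoulli dim
  # (p 0.1 vs 0.9); all other dims masked out. Observation (3, 1).
  mu <- matrix(0, 2, 96); mu[2, 1] <- 3
  s2 <- matrix(1, 2, 96)
  p <- matrix(0.5, 2, 96); p[, 1] <- c(0.1, 0.9)
  model <- hetmix_model(c(0.5, 0.5), mu, s2, p)
  x <- rep(0, 192); x[1] <- 3; x[97] <- 1
  mask <- rep(FALSE, 192); mask[c(1, 97)] <- TRUE
  ll <- day_loglik(model, x, mask)
  post <- exp(ll) * model$weights / sum(exp(ll) * model$weights)
  lik <- c(dnorm(3, 0, 1) * 0.1, dnorm(3, 3, 1) * 0.9)
  expect_equal(post, lik / sum(lik), tolerance = 1e-12)

  # K = 1: responsibility 1 regardless of data
  m1 <- hetmix_model(1, mu[1, , drop = FALSE], s2[1, , drop = FALSE],
                     p[1, , drop = FALSE])
  f <- simulate_features(rep(1, 10), m1$mu, sqrt(m1$sigma2), m1$p, seed = 2)
  pp <- profile_posterior(m1, f)
  expect_true(all(pp$prob == 1))
})

test_that("K = 1 EM equals the closed-form observed-data MLE", {
  em <- separated_emissions(1, sigma = 0.3)
  f <- simulate_features(rep(1, 40), em$mu, em$sigma, em$p, seed = 3)
  fit <- em_fit(f, 1, n_restarts = 1, seed = 1)
  xc <- cbind(f$distance, f$steps)
  xb <- cbind(f$home, f$app)
  expect_equal(fit$weights, 1)
  expect_equal(as.vector(fit$mu), colMeans(xc), tolerance = 1e-10)
  v <- colMeans(sweep(xc, 2, colMeans(xc))^2)
  expect_equal(as.vector(fit$sigma2), pmax(v, 1e-4), tolerance = 1e-10)
  expect_equal(as.vector(fit$p),
               pmin(pmax(colMeans(xb), 1e-3), 1 - 1e-3), tolerance = 1e-10)
})

test_that("EM log-likelihood is monotone and duplication leaves the fit alone", {
  em <- separated_emissions(2)
  f <- simulate_features(rep(1:2, 30), em$mu, em$sigma, em$p, seed = 5)
  fit <- em_fit(f, 2, n_restarts = 3, seed = 9)
  tr <- attr(fit, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))

  # duplicating every day is sufficiency-preserving
  dup <- function(m) m[rep(seq_len(nrow(m)), each = 2), ]
  f2 <- daily_features("d", seq_len(120) - 1L, dup(f$distance), dup(f$steps),
                       dup(f$home), dup(f$app), lapply(f$mask, dup))
  fit2 <- em_fit(f2, 2, n_restarts = 3, seed = 9)
  perm <- if (abs(fit2$mu[1, 1] - fit$mu[1, 1]) <
              abs(fit2$mu[2, 1] - fit$mu[1, 1])) 1:2 else 2:1
  expect_equal(fit2$mu[perm, ], fit$mu, tolerance = 1e-3)
  expect_equal(fit2$weights[perm], fit$weights, tolerance = 1e-3)
})

test_that("well-separated two-profile means are recovered", {
  em <- separated_emissions(2, sigma = 0.15)   # gaps >= 5 sigma
  set.seed(11)
  labels <- sample(1:2, 120, replace = TRUE)
  f <- simulate_features(labels, em$mu, em$sigma, em$p, seed = 11)
  fit <- em_fit(f, 2, n_restarts = 3, seed = 2)
  perm <- if (sum(abs(fit$mu[1, ] - em$mu[1, ])) <
              sum(abs(fit$mu[1, ] - em$mu[2, ]))) 1:2 else 2:1
  expect_lt(max(abs(fit$mu[perm, ] - em$mu)), 0.1)
})

test_that("insufficient usable days raise an error", {
  em <- separated_emissions(2)
  f <- simulate_features(c(1, 2), em$mu, em$sigma, em$p, seed = 1)
  expect_error(em_fit(f, 3), "insufficient data")
})

test_that("BIC behaves as a penalized likelihood", {
  em <- separated_emissions(1, sigma = 0.2)
  f <- simulate_features(rep(1, 60), em$mu, em$sigma, em$p, seed = 6)
  fit1 <- em_fit(f, 1, n_restarts = 1, seed = 1)
  fit2 <- em_fit(f, 2, n_restarts = 2, seed = 1)
  expect_lt(bic_score(fit1, f), bic_score(fit2, f))   # penalty dominates

  # same loglik, more parameters -> strictly worse BIC
  dup <- hetmix_model(c(0.5, 0.5), rbind(fit1$mu, fit1$mu),
                      rbind(fit1$sigma2, fit1$sigma2), rbind(fit1$p, fit1$p))
  attr(dup, "loglik") <- attr(fit1, "loglik")
  expect_gt(bic_score(dup, f), bic_score(fit1, f))

  # n_days = 1, K = 1: BIC = -2 loglik exactly (log(1) = 0)
  f1 <- simulate_features(1, em$mu, em$sigma, em$p, seed = 7)
  fit_a <- em_fit(f1, 1, n_restarts = 1, seed = 1)
  expect_equal(bic_score(fit_a, f1), -2 * attr(fit_a, "loglik"))
})

test_that("select_profiles recovers K and degenerates gracefully", {
  # K_true = 3, strongly separated (quick 5-run version; the 20-run
  # experiment is in the acceptance suite)
  hits <- 0
  for (r in 1:5) {
    em <- separated_emissions(3)
    set.seed(300 + r)
    labels <- sample(1:3, 120, replace = TRUE)
    f <- simulate_features(labels, em$mu, em$sigma, em$p, seed = 300 + r)
    sel <- select_profiles(f, K_max = 5, n_restarts = 2, seed = r)
    hits <- hits + (sel$K == 3)
  }
  expect_gte(hits, 4)

  # constant identical days -> K = 1
  em1 <- separated_emissions(1, sigma = 0.05)
  f_const <- simulate_features(rep(1, 50), em1$mu,
                               matrix(0.05, 1, 96), em1$p, seed = 9)
  expect_identical(select_profiles(f_const, K_max = 3, n_restarts = 2,
                                   seed = 1)$K, 1L)

  # K_max = 1 -> all-ones posterior
  sel1 <- select_profiles(f_const, K_max = 1, seed = 1)
  expect_true(all(sel1$posterior$prob == 1))
})

test_that("posterior rows are simplex and missing rows equal the weights", {
  em <- separated_emissions(2)
  f <- simulate_features(rep(1:2, 25), em$mu, em$sigma, em$p, seed = 13)
  # blank out two days entirely
  for (v in c("distance", "steps", "home", "app")) {
    f$mask[[v]][c(5, 20), ] <- FALSE
    f[[v]][c(5, 20), ] <- NA
  }
  fit <- em_fit(f, 2, n_restarts = 2, seed = 3)
  pp <- profile_posterior(fit, f)
  expect_equal(rowSums(pp$prob), rep(1, 50), tolerance = 1e-9)
  expect_equal(pp$prob[5, ], fit$weights, tolerance = 1e-12)
  expect_equal(pp$prob[20, ], fit$weights, tolerance = 1e-12)
  expect_identical(which(pp$missing), c(5L, 20L))
})

test_that("component relabeling permutes posteriors and preserves BIC", {
  em <- separated_emissions(2)
  f <- simulate_features(rep(1:2, 20), em$mu, em$sigma, em$p, seed = 17)
  fit <- em_fit(f, 2, n_restarts = 2, seed = 5)
  swapped <- hetmix_model(fit$weights[2:1], fit$mu[2:1, ], fit$sigma2[2:1, ],
                          fit$p[2:1, ])
  expect_equal(bic_score(swapped, f), bic_score(fit, f), tolerance = 1e-8)
  expect_equal(profile_posterior(swapped, f)$prob,
               profile_posterior(fit, f)$prob[, 2:1], tolerance = 1e-10)
})
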