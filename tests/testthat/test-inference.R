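test_that("prior sampling is reproducible, correct for point masses, and unbiased", {
  pr <- prior_spec(a = prior_point(3.5), b = prior_uniform(2, 6))
  s1 <- sample_prior(pr, 100, seed = 4)
  s2 <- sample_prior(pr, 100, seed = 4)
  expect_identical(s1, s2)                       # bitwise reproducibility
  expect_equal(s1$a, rep(3.5, 100))

  n <- 1e5
  s <- sample_prior(prior_spec(b = prior_uniform(2, 6)), n, seed = 9)
  # CLT bound: |mean - 4| < 3 * (b - a) / sqrt(12 n)
  expect_lt(abs(mean(s$b) - 4), 3 * 4 / sqrt(12 * n))
  expect_true(all(s$b >= 2 & s$b <= 6))
})

test_that("invalid prior descriptors are rejected", {
  expect_error(prior_spec(list(prior_uniform(0, 1))), "configuration error")
  expect_error(prior_spec(a = list(dist = "cauchy")), "configuration error")
  expect_error(prior_spec(a = list(dist = "uniform", min = 2, max = 1)),
               "configuration error")
})

test_that("the Gaussian log-likelihood matches its definition and a naive loop", {
  t <- seq(0, 10, by = 0.5)
  w <- 0.3 + 0.1 * sin(t)
  sim <- observation_series(t, w, depth = 14)
  obs <- observation_series(t, w, depth = 14)
  expect_equal(as.numeric(log_likelihood(sim, obs, sigma_area = 1)), 0)

  # single point with a one-sigma residual
  sigma_w <- 1 / 14
  sim1 <- observation_series(0, 0.5, depth = 14)
  obs1 <- observation_series(0, 0.5 + sigma_w, depth = 14)
  expect_equal(as.numeric(log_likelihood(sim1, obs1, sigma_area = 1)), -0.5)

  # vector of residuals against an explicit loop oracle
  set.seed(21)
  w2 <- w + rnorm(length(w), 0, 0.05)
  obs2 <- observation_series(t, pmax(0, w2), depth = 14)
  ll <- log_likelihood(sim, obs2, sigma_area = 2, max_lag = 0)
  acc <- 0
  for (i in seq_along(t)) acc <- acc - 0.5 * ((obs2$width_mm[i] - w[i]) / (2 / 14))^2
  expect_equal(as.numeric(ll), acc, tolerance = 1e-12)
})

test_that("weights are invariant to constants and zero out failures", {
  ll <- c(-5, -3, NA, -4)
  w1 <- importance_weights(ll)
  w2 <- importance_weights(ll + 1234.5)
  expect_equal(w1, w2, tolerance = 1e-12)
  expect_equal(w1[3], 0)
  expect_equal(sum(w1), 1)
  expect_error(importance_weights(c(NA_real_, NA_real_)), "degenerate")
})

test_that("estimates are invariant to permuting the ensemble order", {
  set.seed(2)
  samples <- tibble::tibble(a = rnorm(200, 5), b = runif(200))
  ll <- -((samples$a - 5.2)^2) / 0.1
  p1 <- posterior_from_ensemble(samples, ll, resample_seed = 3)
  perm <- sample.int(200)
  p2 <- posterior_from_ensemble(samples[perm, ], ll[perm], resample_seed = 3)
  expect_equal(tidy(p1)$estimate, tidy(p2)$estimate, tolerance = 1e-12)
  expect_equal(tidy(p1)$std, tidy(p2)$std, tolerance = 1e-12)
  expect_equal(p1$n_eff, p2$n_eff, tolerance = 1e-12)
})

test_that("uniform weights reproduce the sample mean under resampling", {
  set.seed(8)
  samples <- tibble::tibble(a = rnorm(2000, 1, 0.5))
  p <- posterior_from_ensemble(samples, rep(-1, 2000), resample_seed = 5)
  expect_equal(tidy(p)$estimate, mean(samples$a), tolerance = 1e-12)
  rs <- samples$a[p$resample_idx]
  expect_lt(abs(mean(rs) - mean(samples$a)), 4 * sd(samples$a) / sqrt(2000))
  expect_equal(length(p$resample_idx), 2000)
  expect_equal(p$n_eff, 2000)
})

test_that("a near-degenerate likelihood concentrates on the generating sample", {
  pr <- prior_spec(x = prior_uniform(0, 1))
  samples <- sample_prior(pr, 50, seed = 31)
  target <- samples$x[17]
  forward <- function(theta) observation_series(0, theta[["x"]], depth = 1)
  obs <- observation_series(0, target, depth = 1)
  post <- importance_estimate(pr, obs, forward, n = 50, seed = 31,
                              sigma_area = 1e-6)
  expect_equal(max(post$weights), 1, tolerance = 1e-6)
  expect_equal(tidy(post)$estimate, target, tolerance = 1e-9)
})

test_that("the conjugate-Gaussian toy recovers the closed-form posterior", {
  mu0 <- 2; s0 <- 0.5
  sigma <- 0.3
  y <- 2.6
  n <- 1e4
  pr <- prior_spec(x = prior_normal(mu0, s0))
  forward <- function(theta) observation_series(0, theta[["x"]], depth = 1)
  obs <- observation_series(0, y, depth = 1)
  post <- importance_estimate(pr, obs, forward, n = n, seed = 12,
                              sigma_area = sigma)
  # closed-form Gaussian-conjugate posterior mean and sd
  prec <- 1 / s0^2 + 1 / sigma^2
  mu_post <- (mu0 / s0^2 + y / sigma^2) / prec
  # Monte-Carlo standard error of the weighted mean
  sm <- tidy(post)
  mcse <- sqrt(sum(post$weights^2 * (post$samples$x - sm$estimate)^2))
  expect_lt(abs(sm$estimate - mu_post), 3 * mcse)
  expect_equal(sm$std, sqrt(1 / prec), tolerance = 0.1)
  expect_gt(post$n_eff, 100)
})

test_that("conjugate coverage: truth within 2 posterior sd in >= 90% of seeds", {
  mu0 <- 1; s0 <- 0.4; sigma <- 0.25
  pr <- prior_spec(x = prior_normal(mu0, s0))
  forward <- function(theta) observation_series(0, theta[["x"]], depth = 1)
  covered <- logical(20)
  set.seed(99)
  truths <- rnorm(20, mu0, s0)
  for (k in 1:20) {
    y <- truths[k] + rnorm(1, 0, sigma)
    obs <- observation_series(0, max(0, y), depth = 1)
    post <- importance_estimate(pr, obs, forward, n = 2000, seed = 100 + k,
                                sigma_area = sigma)
    sm <- tidy(post)
    covered[k] <- abs(truths[k] - sm$estimate) <= 2 * sm$std
  }
  expect_gte(mean(covered), 0.9)
})

test_that("failed forward runs get zero weight and are counted", {
  pr <- prior_spec(x = prior_uniform(0, 1))
  forward <- function(theta) {
    if (theta[["x"]] > 0.8) stop("boom")
    observation_series(0, theta[["x"]], depth = 1)
  }
  obs <- observation_series(0, 0.4, depth = 1)
  post <- importance_estimate(pr, obs, forward, n = 200, seed = 6,
                              sigma_area = 0.5)
  expect_gt(post$n_failures, 0)
  failed <- is.na(post$log_lik)
  expect_true(all(post$weights[failed] == 0))
})

test_that("glance and tidy expose the posterior summaries", {
  samples <- tibble::tibble(a = 1:10 / 10)
  p <- posterior_from_ensemble(samples, rep(0, 10),
                               truth = list(a = 0.5))
  g <- glance(p)
  expect_named(g, c("n", "n_eff", "failures", "max_log_lik"))
  td <- tidy(p)
  expect_equal(td$normalized_estimate, td$estimate / 0.5)
  expect_equal(td$relative_uncertainty_pct, 100 * td$std / td$estimate)
})
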