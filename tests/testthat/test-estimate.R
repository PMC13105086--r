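test_that("estimate_tau0 matches hand arithmetic and algebraic cases", {
  # numerator = 3 * denominator when Y = 3Z and mu_hat = 3 e_hat
  set.seed(1)
  e <- runif(50, 0.2, 0.8)
  Z <- rbinom(50, 1, e)
  expect_equal(estimate_tau0(3 * Z, Z, 3 * e, e), 3)
  # four-term direct computation
  Z4 <- c(1, 0, 1, 0); e4 <- rep(0.5, 4)
  Y4 <- c(2, 1, 3, 0); mu4 <- c(1.5, 0.5, 2.5, 0.5)
  # residuals (.5,.5,.5,-.5), d = (.5,-.5,.5,-.5): num 0.5, den 1
  expect_equal(estimate_tau0(Y4, Z4, mu4, e4), 0.5)
  expect_error(estimate_tau0(Y4, Z4, mu4, Z4), "degenerate overlap")
})

test_that("estimate_tau0 is consistent under the null with exact nuisances", {
  d <- simulate_hte(2e4, p = 5, sigma = 1, "zero", seed = 8)
  mu <- d$truth$f  # mu = E[Y|X] = f since tau = 0
  expect_lt(abs(estimate_tau0(d$Y, d$Z, mu, d$truth$e)), 0.05)
})

test_that("double robustness: true propensity tolerates a wrong mu_hat", {
  d <- simulate_hte(1e4, p = 5, sigma = 1, "constant3", seed = 13)
  wrong_mu <- rep(0, length(d$Y))
  expect_lt(abs(estimate_tau0(d$Y, d$Z, wrong_mu, d$truth$e) - 3), 0.05)
  # an arbitrary X-measurable mu_hat also cancels
  wrong_mu2 <- 2 * d$X[, 1] - d$X[, 2]^2
  expect_lt(abs(estimate_tau0(d$Y, d$Z, wrong_mu2, d$truth$e) - 3), 0.05)
})

test_that("center_outcome subtracts the constant effect", {
  expect_equal(center_outcome(c(5, 5), c(1, 0), 3), c(2, 5))
  Y <- rnorm(10); Z <- rbinom(10, 1, 0.5)
  expect_equal(center_outcome(Y, Z, 0), Y)
  expect_equal(center_outcome(Y, rep(0, 10), 7), Y)
})

test_that("global revised estimate reduces to tau0 with orthogonal residuals", {
  Z <- c(1, 0, 1, 0); e <- rep(0.5, 4)
  tau0 <- 1.2
  # choose mu_star so that (Y - tau0 Z - mu_star) is orthogonal to Z - e
  Y <- c(3, 1, 2, 0)
  mu_star <- Y - tau0 * Z
  expect_equal(estimate_tau_star_global(Y, Z, mu_star, e, tau0), tau0)
  # hand case: same fixture as estimate_tau0 with tau0 = 0
  expect_equal(estimate_tau_star_global(c(2, 1, 3, 0), Z,
                                        c(1.5, 0.5, 2.5, 0.5), e, 0), 0.5)
})

test_that("global revised estimate converges under a constant effect", {
  d <- simulate_hte(2e4, p = 5, sigma = 1, "constant3", seed = 17)
  mu <- 3 * d$truth$e + d$truth$f
  tau0 <- estimate_tau0(d$Y, d$Z, mu, d$truth$e)
  mu_star <- d$truth$f  # E[Y - 3Z | X] when tau0 is exact
  ts <- estimate_tau_star_global(d$Y, d$Z, mu_star, d$truth$e, tau0)
  expect_lt(abs(ts - 3), 0.06)
})

test_that("log_mse matches direct computation", {
  expect_equal(log_mse(rep(1, 5), rep(0, 5)), 0)
  expect_equal(log_mse(rep(2, 5), rep(0, 5)), log(4))
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(log_mse(a, b), log(sum((a - b)^2) / 20))
  expect_identical(log_mse(a, a), -Inf)
  expect_error(log_mse(a, a, zero = "error"), "exactly zero")
})

test_that("revised fit satisfies tau_star = tau0 + r_hat and stores mu_star", {
  d <- simulate_hte(200, p = 5, sigma = 1, "constant3", seed = 23)
  nuis <- cross_fit(d, c("e", "mu"), K = 4, learner = ridge_learner(),
                    seed = 23)
  fit <- fit_revised(d, nuis, seed = 23)
  expect_s3_class(fit, "hte_fit")
  expect_equal(fit$tau_star - fit$r_hat, rep(fit$tau0, 200))
  expect_length(fit$mu_star_hat, 200)
  expect_true(all(is.finite(fit$tau_star)))
})

test_that("heterogeneity amplitude orders constant vs complex scenarios", {
  # r_hat should be nearly flat when the truth is constant and variable
  # when the truth is heterogeneous, at matched n, p, sigma
  dc <- simulate_hte(800, p = 5, sigma = 1, "constant3", seed = 29)
  dh <- simulate_hte(800, p = 5, sigma = 1, "complex_hte", seed = 29)
  fit_c <- fit_revised(dc, truth_nuisances(dc, K = 4, seed = 29), seed = 29)
  fit_h <- fit_revised(dh, truth_nuisances(dh, K = 4, seed = 29), seed = 29)
  expect_lt(var(fit_c$r_hat), var(fit_h$r_hat))
})

test_that("unrevised R-learner recovers a constant effect with exact nuisances", {
  d <- simulate_hte(2000, p = 5, sigma = 1, "constant3", seed = 37)
  fit <- fit_r_learner(d, truth_nuisances(d, K = 5, seed = 37), seed = 37)
  expect_equal(fit$variant, "unrevised")
  expect_lt(abs(mean(fit$tau_star) - 3), 0.2)
})

test_that("new-data prediction averages fold models", {
  d <- simulate_hte(300, p = 5, sigma = 1, "simple_hte", seed = 41)
  nuis <- cross_fit(d, c("e", "mu"), K = 3, learner = ridge_learner(),
                    seed = 41)
  fit <- fit_revised(d, nuis, keep_models = TRUE, seed = 41)
  newX <- simulate_hte(50, p = 5, seed = 43)$X
  pred <- predict(fit, newX)
  expect_length(pred, 50)
  expect_true(all(is.finite(pred)))
  fit0 <- fit_revised(d, nuis, keep_models = FALSE, seed = 41)
  expect_error(predict(fit0, newX), "keep_models")
})
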