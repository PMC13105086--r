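test_that("projection matrix is a rank n-1 orthogonal projector", {
  set.seed(1)
  a <- runif(30, 0.1, 1)
  P <- projection_matrix(a)
  expect_lt(max(abs(P %*% P - P)), 1e-10)
  expect_lt(max(abs(t(P) - P)), 1e-12)
  expect_lt(sqrt(sum((P %*% a)^2)), 1e-10)
  expect_equal(sum(diag(P)), length(a) - 1)
  expect_error(projection_matrix(rep(0, 5)), "zero vector")
})

test_that("RBF kernel has unit diagonal, symmetry and is PSD", {
  set.seed(2)
  X <- matrix(rnorm(50 * 5), 50, 5)
  K <- rbf_kernel_matrix(X)
  expect_equal(diag(K), rep(1, 50))
  expect_lt(max(abs(K - t(K))), 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  # duplicated rows give kernel value 1
  X2 <- rbind(X, X[1, ])
  K2 <- rbf_kernel_matrix(X2)
  expect_equal(K2[1, 51], 1)
  expect_error(rbf_kernel_matrix(matrix(c(1, NA, 0, 1), 2, 2)), "non-finite")
  expect_gt(attr(rbf_kernel_matrix(X, bandwidth = 2), "bandwidth"), 0)
})

test_that("scores sum to zero and satisfy the constraint a' s = 0", {
  d <- simulate_hte(400, p = 5, sigma = 1, "constant3", seed = 5)
  e <- d$truth$e
  mu <- 3 * e + d$truth$f
  tau0 <- estimate_tau0(d$Y, d$Z, mu, e)
  mu_star <- d$truth$f
  ts <- estimate_tau_star_global(d$Y, d$Z, mu_star, e, tau0)
  sc <- compute_scores(d$Y, d$Z, e, mu_star, tau0, ts)
  expect_lt(abs(sum(sc$u)), 1e-9 * sum(abs(sc$u)))
  expect_lt(abs(sum(sqrt(sc$w) * sc$s)), 1e-8)
  expect_gt(sc$sigma2_hat, 0)
})

test_that("studentized scores have unit scale under the null", {
  d <- simulate_hte(5000, p = 5, sigma = 1, "zero", seed = 7)
  e <- d$truth$e; mu <- d$truth$f
  tau0 <- estimate_tau0(d$Y, d$Z, mu, e)
  ts <- estimate_tau_star_global(d$Y, d$Z, mu, e, tau0)
  sc <- compute_scores(d$Y, d$Z, e, mu, tau0, ts)
  expect_lt(abs(var(sc$s) - 1), 0.05)
})

test_that("chi-square mixture tail matches closed forms", {
  expect_equal(as.numeric(davies_pvalue(qchisq(0.95, 1), 1)), 0.05,
               tolerance = 1e-4)
  expect_equal(as.numeric(davies_pvalue(qchisq(0.95, 2), c(1, 1))), 0.05,
               tolerance = 1e-4)
  expect_equal(as.numeric(davies_pvalue(3.8415, 1)),
               pchisq(3.8415, 1, lower.tail = FALSE), tolerance = 1e-5)
  # scale equivariance: lambda * chi2_1 at lambda * q
  expect_equal(as.numeric(davies_pvalue(2.7 * 3, 2.7)),
               pchisq(3, 1, lower.tail = FALSE), tolerance = 1e-5)
  expect_equal(as.numeric(davies_pvalue(0, c(1, 2))), 1)
  expect_error(davies_pvalue(1, c(1, -0.5)), "negative")
})

test_that("mixture tail agrees with Monte-Carlo simulation", {
  set.seed(11)
  for (i in 1:4) {
    lam <- sort(runif(sample(2:5, 1), 0.2, 3), decreasing = TRUE)
    draws <- as.vector(matrix(rchisq(2e5 * length(lam), 1), ncol = length(lam)) %*% lam)
    q <- quantile(draws, 0.9)
    p_mc <- mean(draws >= q)
    expect_lt(abs(as.numeric(davies_pvalue(q, lam)) - p_mc), 0.01)
  }
})

test_that("kernel score statistic matches the explicit projection form", {
  d <- simulate_hte(150, p = 5, sigma = 1, "zero", seed = 13)
  nuis <- truth_nuisances(d, K = 3, seed = 13)
  res <- kernel_score_test(d, nuis, variant = "unrevised")
  P <- projection_matrix(sqrt(res$w))
  K <- rbf_kernel_matrix(d$X)
  Q_explicit <- as.numeric(t(res$s) %*% P %*% K %*% P %*% res$s)
  expect_equal(res$Q, Q_explicit, tolerance = 1e-8)
  expect_equal(res$k_eff, sum(res$lambdas)^2 / sum(res$lambdas^2))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_gte(res$Q, 0)
})

test_that("identity kernel gives Q = |Ps|^2 and a degenerate kernel p = 1", {
  d <- simulate_hte(100, p = 5, sigma = 1, "zero", seed = 17)
  nuis <- truth_nuisances(d, K = 2, seed = 17)
  res <- kernel_score_test(d, nuis, variant = "unrevised",
                           kernel_matrix = diag(100))
  a <- sqrt(res$w)
  s_t <- res$s - a * sum(a * res$s) / sum(a^2)
  expect_equal(res$Q, sum(s_t^2), tolerance = 1e-10)
  expect_warning(
    res0 <- kernel_score_test(d, nuis, variant = "unrevised",
                              kernel_matrix = matrix(0, 100, 100)),
    "below tolerance")
  expect_equal(res0$p_value, 1)
})

test_that("revised and unrevised variants share the mixture weights", {
  d <- simulate_hte(200, p = 5, sigma = 1, "constant3", seed = 19)
  nuis <- cross_fit(d, c("e", "mu"), K = 4, learner = ridge_learner(),
                    seed = 19)
  fit <- fit_revised(d, nuis, seed = 19)
  r1 <- kernel_score_test(d, nuis, "revised", fit = fit, seed = 19)
  r2 <- kernel_score_test(d, nuis, "unrevised", seed = 19)
  expect_equal(r1$lambdas, r2$lambdas)
  expect_false(isTRUE(all.equal(r1$Q, r2$Q)))
})
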