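make_linear_task <- function(n, p = 5, sigma = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- seq_len(p) / p
  list(X = X, y = drop(X %*% beta) + rnorm(n, 0, sigma), beta = beta)
}

test_that("a single-member bag equals its lone network", {
  task <- make_linear_task(100)
  b <- fit_bagged(task$X, task$y, "regression", n_bags = 1,
                  control = fast_control(), seed = 5)
  expect_equal(predict(b, task$X), predict(b$members[[1]], task$X))
  expect_true(all(b$kept))
})

test_that("a constant regression target is fit to within tolerance", {
  # Adam bounces at a noise floor proportional to the learning rate, so the
  # fit is constant up to that floor, not to machine precision
  set.seed(2)
  X <- matrix(rnorm(200 * 4), 200, 4)
  b <- fit_bagged(X, rep(2.5, 200), "regression", n_bags = 2,
                  control = fast_control(epochs = 300), seed = 2)
  expect_lt(mean(abs(predict(b, X) - 2.5)), 0.1)
  expect_lt(max(abs(predict(b, X) - 2.5)), 0.3)
})

test_that("bagged MLP tracks a linear signal about as well as least squares", {
  task <- make_linear_task(2000, sigma = 0.1)
  hold <- 1601:2000
  b <- fit_bagged(task$X[-hold, ], task$y[-hold], "regression", n_bags = 3,
                  control = fast_control(), seed = 7)
  pred <- predict(b, task$X[hold, ])
  r2 <- 1 - mean((pred - task$y[hold])^2) / var(task$y[hold])
  expect_gt(r2, 0.9)
  # oracle: OLS fit to the same training rows
  ols <- lm.fit(cbind(1, task$X[-hold, ]), task$y[-hold])
  pred_ols <- drop(cbind(1, task$X[hold, ]) %*% ols$coefficients)
  r2_ols <- 1 - mean((pred_ols - task$y[hold])^2) / var(task$y[hold])
  expect_gt(r2, r2_ols - 0.1)
})

test_that("binary task returns clipped probabilities and needs two classes", {
  set.seed(3)
  X <- matrix(rnorm(400 * 5), 400, 5)
  z <- rbinom(400, 1, plogis(X[, 1]))
  b <- fit_bagged(X, z, "binary", n_bags = 2, control = fast_control(),
                  clip_lo = 0.05, seed = 3)
  pr <- predict(b, X)
  expect_true(all(pr >= 0.05 & pr <= 0.95))
  # predictions carry signal in the right direction
  expect_gt(cor(pr, plogis(X[, 1])), 0.5)
  expect_error(fit_bagged(X, rep(1, 400), "binary", n_bags = 2,
                          control = fast_control()), "single class")
  expect_error(fit_bagged(X[1:10, ], z[1:10], "regression"), "at least 20")
})

test_that("bagging is deterministic given the seed and filtering keeps members", {
  task <- make_linear_task(150)
  b1 <- fit_bagged(task$X, task$y, "regression", n_bags = 3,
                   control = fast_control(), seed = 11)
  b2 <- fit_bagged(task$X, task$y, "regression", n_bags = 3,
                   control = fast_control(), seed = 11)
  expect_equal(predict(b1, task$X), predict(b2, task$X))
  expect_gte(sum(b1$kept), 1)
  expect_length(b1$oob_loss, 3)
})

test_that("bagging does not do worse than the median single member", {
  # ensemble-variance-reduction property, checked across several seeds
  worse <- 0
  for (seed in 1:5) {
    set.seed(seed + 100)
    X <- matrix(rnorm(400 * 5), 400, 5)
    y <- sin(X[, 1]) + X[, 2] * X[, 3] + rnorm(400, 0, 0.5)
    hold <- 301:400
    b <- fit_bagged(X[-hold, ], y[-hold], "regression", n_bags = 5,
                    control = fast_control(), seed = seed)
    mse_bag <- mean((predict(b, X[hold, ]) - y[hold])^2)
    mse_members <- vapply(b$members, function(m)
      mean((predict(m, X[hold, ]) - y[hold])^2), 0)
    if (mse_bag > median(mse_members)) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("an over-aggressive filter falls back to the single best member", {
  set.seed(9)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- rnorm(100)
  expect_warning(
    b <- fit_bagged(X, y, "regression", n_bags = 3, filter_threshold = -1,
                    control = mlp_control(hidden = 8, epochs = 20,
                                          batch = 64), seed = 1),
    "single best member")
  expect_equal(sum(b$kept), 1)
  expect_equal(which(b$kept), which.min(b$oob_loss))
})

test_that("ridge learner recovers a linear model and fits binary targets", {
  task <- make_linear_task(500, sigma = 0.2, seed = 4)
  spec <- learner_ridge()
  m <- spec$fit(task$X, task$y, "regression")
  expect_gt(cor(predict(m, task$X), task$y), 0.95)
  set.seed(5)
  z <- rbinom(500, 1, plogis(task$X[, 1]))
  mb <- spec$fit(task$X, z, "binary")
  pr <- predict(mb, task$X)
  expect_true(all(pr > 0 & pr < 1))
  expect_gt(cor(pr, plogis(task$X[, 1])), 0.8)
})
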