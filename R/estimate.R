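#' Doubly robust estimate of a constant treatment effect
#'
#' \deqn{\hat\tau_0 = \frac{\sum_i (Y_i - \hat\mu_i)(Z_i - \hat e_i)}
#'                         {\sum_i (Z_i - \hat e_i)^2}}
#' the residual-on-residual slope of the Robinson transformation; consistent
#' for the constant effect when either nuisance is correct.
#'
#' @param Y Outcome vector.
#' @param Z Binary treatment vector.
#' @param mu_hat Cross-fitted outcome-regression predictions.
#' @param e_hat Cross-fitted propensity predictions.
#' @return Scalar estimate.
#' @export
estimate_tau0 <- function(Y, Z, mu_hat, e_hat) {
  stopifnot(length(Y) == length(Z), length(Y) == length(mu_hat),
            length(Y) == length(e_hat))
  d <- Z - e_hat
  den <- sum(d^2)
  if (den <= .Machine$double.eps * length(Y))
    stop("degenerate overlap: sum (Z - e_hat)^2 is zero", call. = FALSE)
  sum((Y - mu_hat) * d) / den
}

#' Center the outcome by removing the constant treatment effect
#'
#' Returns \eqn{Y^* = Y - \tau_0 Z}. After centering, a large homogeneous
#' effect no longer splits the outcome into two arms, so the centered outcome
#' regression \eqn{\mu^*(X) = E[Y^* \mid X]} is a smooth (unimodal-residual)
#' target that flexible learners fit accurately.
#'
#' @inheritParams estimate_tau0
#' @param tau0 Constant-effect estimate.
#' @return Numeric vector `Y - tau0 * Z`.
#' @export
center_outcome <- function(Y, Z, tau0) {
  stopifnot(length(Y) == length(Z))
  Y - tau0 * Z
}

#' Bias-corrected global (constant) effect estimate
#'
#' \deqn{\hat\tau^* = \hat\tau_0 + \frac{\sum_i (Y_i - \hat\tau_0 Z_i -
#'   \hat\mu^*_i)(Z_i - \hat e_i)}{\sum_i (Z_i - \hat e_i)^2}}
#' the constant-effect estimate recomputed from the centered outcome
#' regression; the correction term vanishes when the centered residuals are
#' orthogonal to the treatment residual.
#'
#' @inheritParams estimate_tau0
#' @param mu_star_hat Cross-fitted centered outcome regression
#'   \eqn{\hat\mu^*(X_i)}.
#' @param tau0 First-stage constant-effect estimate.
#' @return Scalar estimate.
#' @export
estimate_tau_star_global <- function(Y, Z, mu_star_hat, e_hat, tau0) {
  d <- Z - e_hat
  den <- sum(d^2)
  if (den <= .Machine$double.eps * length(Y))
    stop("degenerate overlap: sum (Z - e_hat)^2 is zero", call. = FALSE)
  tau0 + sum((Y - tau0 * Z - mu_star_hat) * d) / den
}

#' Logarithmic mean squared error
#'
#' `log(mean((tau_hat - tau_true)^2))`, the accuracy metric used by the
#' simulation experiments.
#'
#' @param tau_hat,tau_true Equal-length numeric vectors.
#' @param zero `"minus_inf"` (default) returns `-Inf` when the MSE is exactly
#'   zero; `"error"` raises an error instead.
#' @return Scalar.
#' @export
log_mse <- function(tau_hat, tau_true, zero = c("minus_inf", "error")) {
  zero <- match.arg(zero)
  stopifnot(length(tau_hat) == length(tau_true), length(tau_hat) >= 1)
  mse <- mean((tau_hat - tau_true)^2)
  if (mse == 0 && zero == "error") stop("MSE is exactly zero", call. = FALSE)
  log(mse)
}

#' R-learner estimation of heterogeneous treatment effects
#'
#' `fit_r_learner()` is the plain (unrevised) R-learner: it minimises the
#' Robinson squared loss
#' \deqn{\frac1n \sum_i \{(Y_i - \hat\mu_i) - \tau(X_i)(Z_i - \hat e_i)\}^2}
#' over the learner's function class. `fit_revised()` first estimates the
#' constant component \eqn{\hat\tau_0}, centers the outcome
#' \eqn{Y^* = Y - \hat\tau_0 Z}, cross-fits the centered outcome regression
#' \eqn{\hat\mu^*(X)}, then estimates the residual heterogeneity
#' \eqn{\hat r(X)} from the centered loss and returns
#' \eqn{\hat\tau^*(X) = \hat\tau_0 + \hat r(X)}.
#'
#' Both minimisations are carried out as weighted regressions: the
#' pseudo-outcome (residual divided by \eqn{Z_i - \hat e_i}) is regressed on
#' \eqn{X} with weights \eqn{w_i = (Z_i - \hat e_i)^2}, which is algebraically
#' identical to the squared losses above and lets any weighted regression
#' learner be plugged in. Effect predictions for the original subjects are
#' strictly out-of-fold, reusing the nuisance fold partition.
#'
#' @param data An `hte_data` object (or list with `X`, `Z`, `Y`).
#' @param nuisances A [cross_fit()] result containing `e_hat` and `mu_hat`.
#' @param learner Learner for the effect regression (and, for
#'   `fit_revised()`, the centered outcome regression); defaults to the
#'   learner stored in `nuisances`.
#' @param keep_models Keep per-fold effect models for new-data prediction.
#' @param seed Integer seed for the effect-stage fits.
#' @return An object of class `hte_fit`: list with `variant`, `tau0`,
#'   `tau_star_global`, out-of-fold effect predictions `tau_star` (and
#'   `r_hat` for the revised variant), `mu_star_hat` (revised), `fold_of`,
#'   and per-fold models when requested.
#' @export
fit_r_learner <- function(data, nuisances, learner = NULL,
                          keep_models = FALSE, seed = 1L) {
  learner <- learner %||% nuisances$learner
  X <- as.matrix(data$X); Z <- data$Z; Y <- data$Y
  e_hat <- nuisances$e_hat; mu_hat <- nuisances$mu_hat
  stopifnot(!is.null(e_hat), !is.null(mu_hat))
  tau0 <- estimate_tau0(Y, Z, mu_hat, e_hat)
  d <- Z - e_hat
  fit <- cross_fit_target(X, (Y - mu_hat) / d, "regression",
                          nuisances$fold_of, learner, weights = d^2,
                          seed = seed + 101L, keep_models = keep_models)
  out <- list(variant = "unrevised", tau0 = tau0, tau_star_global = tau0,
              tau_star = fit$pred, r_hat = NULL, mu_star_hat = NULL,
              fold_of = nuisances$fold_of, models = fit$models,
              e_hat = e_hat, mu_hat = mu_hat)
  class(out) <- "hte_fit"
  out
}

#' @rdname fit_r_learner
#' @export
fit_revised <- function(data, nuisances, learner = NULL,
                        keep_models = FALSE, seed = 1L) {
  learner <- learner %||% nuisances$learner
  X <- as.matrix(data$X); Z <- data$Z; Y <- data$Y
  e_hat <- nuisances$e_hat; mu_hat <- nuisances$mu_hat
  stopifnot(!is.null(e_hat), !is.null(mu_hat))
  tau0 <- estimate_tau0(Y, Z, mu_hat, e_hat)
  Y_star <- center_outcome(Y, Z, tau0)
  mu_star <- cross_fit_target(X, Y_star, "regression", nuisances$fold_of,
                              learner, seed = seed + 201L,
                              keep_models = keep_models)
  d <- Z - e_hat
  rfit <- cross_fit_target(X, (Y_star - mu_star$pred) / d, "regression",
                           nuisances$fold_of, learner, weights = d^2,
                           seed = seed + 301L, keep_models = keep_models)
  tau_star_global <- estimate_tau_star_global(Y, Z, mu_star$pred, e_hat, tau0)
  out <- list(variant = "revised", tau0 = tau0,
              tau_star_global = tau_star_global,
              tau_star = tau0 + rfit$pred, r_hat = rfit$pred,
              mu_star_hat = mu_star$pred, fold_of = nuisances$fold_of,
              models = rfit$models, mu_star_models = mu_star$models,
              e_hat = e_hat, mu_hat = mu_hat)
  class(out) <- "hte_fit"
  out
}

#' Predict treatment effects for new subjects
#'
#' Averages the K fold-specific effect models (requires the fit to have been
#' run with `keep_models = TRUE`); the revised variant adds back
#' \eqn{\hat\tau_0}.
#'
#' @param object An `hte_fit`.
#' @param newdata Covariate matrix.
#' @param ... Unused.
#' @return Numeric vector of effect predictions.
#' @export
predict.hte_fit <- function(object, newdata, ...) {
  if (is.null(object$models))
    stop("fit was run with keep_models = FALSE; no models stored", call. = FALSE)
  X <- as.matrix(newdata)
  preds <- vapply(object$models, function(m) predict(m, X), numeric(nrow(X)))
  base <- if (is.matrix(preds)) rowMeans(preds) else mean(preds)
  if (object$variant == "revised") object$tau0 + base else base
}

#' @export
print.hte_fit <- function(x, ...) {
  cat(sprintf("hte_fit (%s): tau0 = %.4f, tau_star_global = %.4f, sd(tau_star) = %.4f\n",
              x$variant, x$tau0, x$tau_star_global, stats::sd(x$tau_star)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
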