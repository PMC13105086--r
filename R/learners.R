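#' Hyperparameters for the multilayer-perceptron base learner
#'
#' @param hidden Integer vector of hidden-layer widths (ReLU activations).
#' @param epochs Maximum training epochs.
#' @param batch Mini-batch size.
#' @param lr Adam learning rate.
#' @param val_frac Fraction of the training rows held out for early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @return A list of class `mlp_control`.
#' @export
mlp_control <- function(hidden = c(50, 50), epochs = 200, batch = 64,
                        lr = 0.005, val_frac = 0.2, patience = 20) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1), epochs >= 1, batch >= 1,
            lr > 0, val_frac >= 0, val_frac < 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, val_frac = val_frac,
                 patience = as.integer(patience)),
            class = "mlp_control")
}

# fit one MLP; standardizes inputs (and the target, for regression) with
# statistics of the rows it is given, so cross-fitting never leaks fold info
fit_mlp <- function(X, y, weights = NULL, task = c("regression", "binary"),
                    control = mlp_control(), seed = 1L) {
  task <- match.arg(task)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- weights / mean(weights)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (task == "regression") {
    y_ctr <- stats::weighted.mean(y, weights)
    y_scl <- sqrt(stats::weighted.mean((y - y_ctr)^2, weights))
    if (!is.finite(y_scl) || y_scl < 1e-12) y_scl <- 1
    ys <- (y - y_ctr) / y_scl
  } else {
    stopifnot(all(y %in% c(0, 1)))
    y_ctr <- 0; y_scl <- 1
    ys <- y
  }
  fit <- .mlp_fit_cpp(Xs, ys, weights, control$hidden,
                      if (task == "regression") 0L else 1L,
                      control$epochs, control$batch, control$lr,
                      control$val_frac, control$patience, as.integer(seed))
  structure(list(net = fit, x_center = ctr, x_scale = scl,
                 y_center = y_ctr, y_scale = y_scl, task = task,
                 val_loss = fit$val_loss, epochs_run = fit$epochs_run),
            class = "htel_mlp")
}

#' @export
predict.htel_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  z <- as.numeric(.mlp_predict_cpp(object$net, Xs))
  if (object$task == "regression") z * object$y_scale + object$y_center else z
}

#' Fit a bagged neural-network ensemble with out-of-bag filtering
#'
#' Trains `n_bags` multilayer perceptrons on bootstrap resamples of the rows,
#' scores each member on its out-of-bag rows (mean squared error for
#' regression, log loss for binary probability), and discards members whose
#' out-of-bag loss exceeds the member median by more than
#' `filter_threshold` (a relative margin). Predictions average the surviving
#' members; binary-probability output is clipped to
#' `[clip_lo, 1 - clip_lo]`. If filtering would discard every member, the
#' single best member is kept with a warning.
#'
#' @param X Covariate matrix (rows = subjects).
#' @param t Target vector; for `task = "binary"` must be 0/1 with both
#'   classes present.
#' @param task `"regression"` or `"binary"`.
#' @param n_bags Number of bootstrap-trained members.
#' @param filter_threshold Relative out-of-bag loss margin for discarding
#'   members (0.2 = 20 percent above the median).
#' @param weights Optional per-row weights carried into each member's loss.
#' @param control An [mlp_control()] block for the base networks.
#' @param clip_lo Probability clipping bound for binary output.
#' @param seed Integer seed; fans out deterministically to bootstrap draws
#'   and member initialisation.
#' @return A `bagged_mlp` object with a `predict()` method.
#' @export
fit_bagged <- function(X, t, task = c("regression", "binary"), n_bags = 20,
                       filter_threshold = 0.2, weights = NULL,
                       control = mlp_control(), clip_lo = 0.01, seed = 1L) {
  task <- match.arg(task)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(t) == n, n_bags >= 1)
  if (n < 20) stop("fit_bagged needs at least 20 rows", call. = FALSE)
  if (task == "binary" && length(unique(t)) < 2)
    stop("binary target has a single class", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  member_seeds <- sample.int(.Machine$integer.max, n_bags)

  members <- vector("list", n_bags)
  oob_loss <- rep(NA_real_, n_bags)
  for (b in seq_len(n_bags)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (task == "binary" && length(unique(t[idx])) < 2)
      idx <- c(idx[-1], which(t != t[idx[1]])[1])  # guarantee both classes
    m <- fit_mlp(X[idx, , drop = FALSE], t[idx], weights[idx], task,
                 control, member_seeds[b])
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) >= 2) {
      pr <- predict(m, X[oob, , drop = FALSE])
      oob_loss[b] <- member_loss(pr, t[oob], weights[oob], task, clip_lo)
    } else {
      oob_loss[b] <- m$val_loss
    }
    members[[b]] <- m
  }
  med <- stats::median(oob_loss)
  kept <- oob_loss <= med * (1 + filter_threshold)
  if (!any(kept)) {
    warning("all ensemble members filtered; keeping the single best member")
    kept <- seq_along(oob_loss) == which.min(oob_loss)
  }
  structure(list(members = members, kept = kept, oob_loss = oob_loss,
                 task = task, clip_lo = clip_lo, n_bags = n_bags,
                 control = control),
            class = "bagged_mlp")
}

member_loss <- function(pred, t, w, task, clip_lo) {
  w <- w / mean(w)
  if (task == "regression") {
    mean(w * (pred - t)^2)
  } else {
    p <- pmin(pmax(pred, clip_lo), 1 - clip_lo)
    -mean(w * (t * log(p) + (1 - t) * log(1 - p)))
  }
}

#' @export
predict.bagged_mlp <- function(object, newdata, ...) {
  preds <- vapply(object$members[object$kept],
                  function(m) predict(m, newdata),
                  numeric(nrow(as.matrix(newdata))))
  out <- if (is.matrix(preds)) rowMeans(preds) else mean(preds)
  if (object$task == "binary")
    out <- pmin(pmax(out, object$clip_lo), 1 - object$clip_lo)
  out
}

#' @export
print.bagged_mlp <- function(x, ...) {
  cat(sprintf("bagged_mlp (%s): %d/%d members kept, median OOB loss %.4g\n",
              x$task, sum(x$kept), x$n_bags, stats::median(x$oob_loss)))
  invisible(x)
}

#' Learner specifications for cross-fitting
#'
#' A learner specification bundles a `fit(X, t, task, weights, seed)` closure
#' so the same learner can be reused for every nuisance and effect regression
#' in the pipeline. `learner_bagged_mlp()` is the default (the bagged
#' neural-network ensemble); `learner_ridge()` is a fast baseline using
#' closed-form weighted ridge regression for continuous targets and logistic
#' regression for binary ones, useful for quick runs and tests.
#'
#' @param n_bags,filter_threshold,control,clip_lo See [fit_bagged()].
#' @param n_bags_binary Ensemble size for binary-probability tasks; defaults
#'   to `n_bags`. The propensity task carries Bernoulli noise on top of a
#'   hard-to-learn surface, so it typically benefits from more
#'   variance-reducing members than the outcome regressions.
#' @param lambda Ridge penalty (on standardized covariates).
#' @return A list of class `hte_learner` with elements `name` and `fit`.
#' @export
learner_bagged_mlp <- function(n_bags = 20, n_bags_binary = NULL,
                               filter_threshold = 0.2,
                               control = mlp_control(), clip_lo = 0.01) {
  n_bags_binary <- n_bags_binary %||% n_bags
  spec <- list(
    name = "bagged_mlp",
    fit = function(X, t, task, weights = NULL, seed = 1L) {
      fit_bagged(X, t, task,
                 n_bags = if (task == "binary") n_bags_binary else n_bags,
                 filter_threshold = filter_threshold, weights = weights,
                 control = control, clip_lo = clip_lo, seed = seed)
    })
  class(spec) <- "hte_learner"
  spec
}

#' @rdname learner_bagged_mlp
#' @export
learner_ridge <- function(lambda = 1e-2, clip_lo = 0.01) {
  spec <- list(
    name = "ridge",
    fit = function(X, t, task, weights = NULL, seed = 1L) {
      fit_ridge(X, t, task, lambda = lambda, weights = weights,
                clip_lo = clip_lo)
    })
  class(spec) <- "hte_learner"
  spec
}

fit_ridge <- function(X, t, task = c("regression", "binary"), lambda = 1e-2,
                      weights = NULL, clip_lo = 0.01) {
  task <- match.arg(task)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (task == "regression") {
    w <- weights / mean(weights)
    Xw <- cbind(1, Xs)
    A <- crossprod(Xw * w, Xw) + lambda * diag(c(0, rep(1, ncol(Xs))))
    beta <- solve(A, crossprod(Xw, w * t))
    obj <- list(beta = beta, task = task)
  } else {
    df <- data.frame(t = t, Xs)
    fit <- suppressWarnings(
      stats::glm(t ~ ., data = df, family = stats::binomial(),
                 weights = weights))
    obj <- list(glm_coef = stats::coef(fit), task = task, clip_lo = clip_lo)
  }
  obj$x_center <- ctr; obj$x_scale <- scl
  class(obj) <- "htel_ridge"
  obj
}

#' @export
predict.htel_ridge <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  if (object$task == "regression") {
    as.numeric(cbind(1, Xs) %*% object$beta)
  } else {
    co <- object$glm_coef
    co[!is.finite(co)] <- 0
    eta <- as.numeric(cbind(1, Xs) %*% co)
    pmin(pmax(stats::plogis(eta), object$clip_lo), 1 - object$clip_lo)
  }
}
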