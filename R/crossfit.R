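#' Partition subjects into K cross-fitting folds
#'
#' Folds are disjoint, cover `1..n`, and differ in size by at most one.
#' With `stratify` supplied (typically the treatment indicator), the split is
#' carried out within each stratum so every fold sees both treatment arms.
#'
#' @param n Number of subjects.
#' @param K Number of folds, `2 <= K <= n`.
#' @param seed Integer seed.
#' @param stratify Optional vector of length `n` of stratum labels.
#' @return Integer vector of length `n` with fold labels in `1..K`.
#' @export
make_folds <- function(n, K = 5, seed = 1L, stratify = NULL) {
  if (K < 2 || K > n) stop("need 2 <= K <= n", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  fold_of <- integer(n)
  if (is.null(stratify)) {
    fold_of <- sample(rep_len(seq_len(K), n))
  } else {
    stopifnot(length(stratify) == n)
    # rotate the fold sequence across strata so sizes stay balanced overall
    offset <- 0L
    for (s in unique(stratify)) {
      idx <- which(stratify == s)
      lab <- ((offset + seq_along(idx) - 1L) %% K) + 1L
      fold_of[idx] <- sample(lab)
      offset <- offset + length(idx)
    }
  }
  fold_of
}

#' Cross-fitted nuisance estimation
#'
#' Estimates the propensity \eqn{e(X) = E[Z \mid X]} and/or the outcome
#' regression \eqn{\mu(X) = E[Y \mid X]} by K-fold cross-fitting: for each
#' fold the learner is trained on the complementary folds and predicts only
#' the held-out subjects, so every prediction is strictly out-of-fold.
#' Folds are stratified on the treatment arm.
#'
#' @param data An `hte_data` object (or list with `X`, `Z`, `Y`).
#' @param targets Which nuisances to fit: subset of `c("e", "mu")`.
#' @param K Number of folds.
#' @param learner An `hte_learner` specification
#'   (default [learner_bagged_mlp()]); reused later for the centered outcome
#'   regression and the effect regressions.
#' @param clip_lo Propensity clipping bound: fitted propensities are kept in
#'   `[clip_lo, 1 - clip_lo]` so the weights \eqn{(Z_i - \hat e_i)^2} stay
#'   away from 0 under poor overlap.
#' @param keep_models Keep the per-fold fitted ensembles (needed to predict
#'   on new data).
#' @param seed Integer master seed; fans out deterministically to the fold
#'   split and each fold's learner.
#' @return An object of class `crossfit_nuisances`: list with `fold_of`,
#'   `e_hat`, `mu_hat` (those requested), the learner spec, `K`, `clip_lo`,
#'   and (optionally) per-fold models.
#' @export
cross_fit <- function(data, targets = c("e", "mu"), K = 5,
                      learner = learner_bagged_mlp(), clip_lo = 0.01,
                      keep_models = FALSE, seed = 1L) {
  stopifnot(all(targets %in% c("e", "mu")))
  X <- as.matrix(data$X); Z <- data$Z; Y <- data$Y
  n <- nrow(X)
  fold_of <- make_folds(n, K, seed = seed, stratify = Z)
  out <- list(fold_of = fold_of, K = K, learner = learner, clip_lo = clip_lo,
              seed = as.integer(seed), models = list())
  if ("e" %in% targets) {
    fit <- cross_fit_target(X, Z, "binary", fold_of, learner,
                            seed = seed + 1L, keep_models = keep_models)
    out$e_hat <- pmin(pmax(fit$pred, clip_lo), 1 - clip_lo)
    out$models$e <- fit$models
  }
  if ("mu" %in% targets) {
    fit <- cross_fit_target(X, Y, "regression", fold_of, learner,
                            seed = seed + 2L, keep_models = keep_models)
    out$mu_hat <- fit$pred
    out$models$mu <- fit$models
  }
  class(out) <- "crossfit_nuisances"
  out
}

# generic K-fold out-of-fold fitter used for e, mu, mu_star, tau and r
cross_fit_target <- function(X, t, task, fold_of, learner, weights = NULL,
                             seed = 1L, keep_models = FALSE) {
  n <- nrow(X)
  K <- max(fold_of)
  pred <- rep(NA_real_, n)
  models <- if (keep_models) vector("list", K) else NULL
  for (k in seq_len(K)) {
    hold <- fold_of == k
    if (task == "binary" && length(unique(t[!hold])) < 2)
      stop("a training split has a single treatment class; use larger folds",
           call. = FALSE)
    m <- learner$fit(X[!hold, , drop = FALSE], t[!hold], task,
                     weights = if (is.null(weights)) NULL else weights[!hold],
                     seed = seed + 31L * k)
    pred[hold] <- predict(m, X[hold, , drop = FALSE])
    if (keep_models) models[[k]] <- m
  }
  list(pred = pred, models = models)
}

#' @export
print.crossfit_nuisances <- function(x, ...) {
  cat(sprintf("crossfit_nuisances: K = %d, learner = %s, targets: %s\n",
              x$K, x$learner$name,
              paste(intersect(c("e_hat", "mu_hat", "mu_star_hat"), names(x)),
                    collapse = ", ")))
  invisible(x)
}
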