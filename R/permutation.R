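#' Cross-fitted prediction loss of an effect model
#'
#' \deqn{L = \frac1n \sum_i \{Y_i - \tau_0 Z_i - m_i -
#'   \hat\tau(X_i)(Z_i - \hat e_i)\}^2,}
#' the out-of-fold mean squared error of the effect regression. For the
#' revised variant pass `tau0` and the centered outcome regression
#' `mu = mu_star_hat` with `tau_pred = tau_star`; for the unrevised variant
#' pass `tau0 = 0`, `mu = mu_hat` and the plain R-learner predictions.
#'
#' @inheritParams estimate_tau0
#' @param mu Out-of-fold outcome-regression predictions.
#' @param tau_pred Out-of-fold effect predictions.
#' @param tau0 Constant-effect estimate used for centering (0 for the
#'   unrevised variant).
#' @return Scalar loss.
#' @export
observed_loss <- function(Y, Z, e_hat, mu, tau_pred, tau0 = 0) {
  stopifnot(length(Y) == length(Z), length(Y) == length(e_hat),
            length(Y) == length(mu), length(Y) == length(tau_pred))
  mean((Y - tau0 * Z - mu - tau_pred * (Z - e_hat))^2)
}

#' Within-arm permutation test for treatment-effect heterogeneity
#'
#' Builds the null distribution of the cross-fitted loss by shuffling the
#' out-of-fold effect predictions among subjects within each
#' (fold, treatment arm) cell. Under the null the covariates carry no
#' heterogeneity signal, so breaking the alignment between subjects and
#' their predicted effects leaves the loss distribution unchanged; under the
#' alternative shuffling destroys the alignment and inflates the permuted
#' loss. The p-value is
#' \deqn{p = \frac{1 + \#\{L^{(b)} \le L_{obs}\}}{B + 1}.}
#'
#' @param data An `hte_data` object (or list with `X`, `Z`, `Y`).
#' @param nuisances A [cross_fit()] result.
#' @param fit An `hte_fit` from [fit_r_learner()] or [fit_revised()] whose
#'   out-of-fold predictions are tested.
#' @param B Number of permutations.
#' @param seed Integer seed; permutation draws are generated in a
#'   deterministic nested order over (replicate, fold, arm).
#' @return An object of class `permutation_result`: list with `L_obs`,
#'   `L_perm`, `B`, `p_value`, `variant`.
#' @export
permutation_test <- function(data, nuisances, fit, B = 1999, seed = 1L) {
  Z <- data$Z; Y <- data$Y
  e_hat <- nuisances$e_hat
  fold_of <- fit$fold_of
  if (fit$variant == "revised") {
    tau0 <- fit$tau0
    mu <- fit$mu_star_hat
  } else {
    tau0 <- 0
    mu <- nuisances$mu_hat
  }
  tau_pred <- fit$tau_star
  base <- Y - tau0 * Z - mu
  d <- Z - e_hat
  L_obs <- mean((base - tau_pred * d)^2)
  if (B < 1) {
    warning("B = 0 permutations; p-value is trivially 1")
    out <- list(L_obs = L_obs, L_perm = numeric(0), B = 0L, p_value = 1,
                variant = fit$variant)
    class(out) <- "permutation_result"
    return(out)
  }
  cells <- split(seq_along(Y), interaction(fold_of, Z, drop = TRUE))
  if (any(lengths(cells) < 1))
    stop("a (fold, arm) cell is empty; cannot permute within arms", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  L_perm <- numeric(B)
  for (b in seq_len(B)) {
    tp <- tau_pred
    for (cell in cells) {
      if (length(cell) > 1) tp[cell] <- tau_pred[sample(cell)]
    }
    L_perm[b] <- mean((base - tp * d)^2)
  }
  out <- list(L_obs = L_obs, L_perm = L_perm, B = as.integer(B),
              p_value = (1 + sum(L_perm <= L_obs)) / (B + 1),
              variant = fit$variant)
  class(out) <- "permutation_result"
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): L_obs = %.4g, B = %d, p = %.4g\n",
              x$variant, x$L_obs, x$B, x$p_value))
  invisible(x)
}
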