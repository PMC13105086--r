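#' Full estimation-and-testing pipeline on one dataset
#'
#' Convenience driver that cross-fits the nuisances, fits the requested
#' effect estimators, and runs the requested heterogeneity tests, sharing
#' the fold partition and the projected-kernel eigenvalues across variants.
#'
#' @param data An `hte_data` object (or list with `X`, `Z`, `Y`).
#' @param K Number of cross-fitting folds.
#' @param learner An `hte_learner` specification used for every regression.
#' @param variants Subset of `c("revised", "unrevised")`.
#' @param tests Subset of `c("analytic", "permutation")`.
#' @param B Number of permutations for the permutation test.
#' @param bandwidth RBF bandwidth for the analytic test.
#' @param keep_models Keep fold models on the effect fits (for new-data
#'   prediction).
#' @param seed Integer master seed.
#' @return An object of class `hte_analysis`: list with `nuisances`, `fits`,
#'   `analytic` and `permutation` (each a named list by variant).
#' @export
#' @examples
#' \donttest{
#' d <- simulate_hte(400, p = 5, seed = 7)
#' res <- hte_analysis(d, K = 2, learner = learner_ridge(),
#'                     tests = "analytic", seed = 7)
#' res$analytic$revised$p_value
#' }
hte_analysis <- function(data, K = 5, learner = learner_bagged_mlp(),
                         variants = c("revised", "unrevised"),
                         tests = c("analytic", "permutation"),
                         B = 1999, bandwidth = "median",
                         keep_models = FALSE, seed = 1L) {
  variants <- match.arg(variants, several.ok = TRUE)
  tests <- match.arg(tests, several.ok = TRUE)
  nuis <- cross_fit(data, c("e", "mu"), K = K, learner = learner,
                    seed = seed)
  out <- list(nuisances = nuis, fits = list(), analytic = list(),
              permutation = list())

  need_fits <- "permutation" %in% tests
  for (v in variants) {
    if (need_fits) {
      out$fits[[v]] <- if (v == "revised") {
        fit_revised(data, nuis, keep_models = keep_models, seed = seed)
      } else {
        fit_r_learner(data, nuis, keep_models = keep_models, seed = seed)
      }
    }
  }

  if ("analytic" %in% tests) {
    Kmat <- rbf_kernel_matrix(data$X, bandwidth = bandwidth)
    # lambdas depend only on X and e_hat, so compute once for both variants
    w <- (data$Z - nuis$e_hat)^2
    lam <- pkp_eigenvalues(Kmat, sqrt(w))
    for (v in variants) {
      out$analytic[[v]] <- kernel_score_test(
        data, nuis, variant = v, fit = out$fits[[v]],
        kernel_matrix = Kmat, lambdas = lam, seed = seed)
    }
  }
  if ("permutation" %in% tests) {
    for (v in variants) {
      out$permutation[[v]] <- permutation_test(data, nuis, out$fits[[v]],
                                               B = B, seed = seed + 7L)
    }
  }
  class(out) <- "hte_analysis"
  out
}

#' @export
print.hte_analysis <- function(x, ...) {
  for (v in names(x$analytic))
    cat(sprintf("analytic  %-9s p = %.4g (Q = %.3g, k_eff = %.1f)\n",
                v, x$analytic[[v]]$p_value, x$analytic[[v]]$Q,
                x$analytic[[v]]$k_eff))
  for (v in names(x$permutation))
    cat(sprintf("permutation %-9s p = %.4g (B = %d)\n",
                v, x$permutation[[v]]$p_value, x$permutation[[v]]$B))
  invisible(x)
}

#' Serialize test results to JSON
#'
#' @param x An `hte_analysis` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
hte_results_json <- function(x, path = NULL) {
  payload <- list()
  for (v in names(x$analytic)) {
    a <- x$analytic[[v]]
    payload[[v]] <- list(Q = a$Q, p_davies = a$p_value, k_eff = a$k_eff,
                         n_lambdas = length(a$lambdas),
                         bandwidth = a$bandwidth, variant = v)
  }
  for (v in names(x$permutation)) {
    pr <- x$permutation[[v]]
    payload[[v]] <- c(payload[[v]],
                      list(L_obs = pr$L_obs, p_perm = pr$p_value, B = pr$B))
    payload[[v]]$variant <- v
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
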