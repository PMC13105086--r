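#' Residual scores for the kernel heterogeneity test
#'
#' Raw residual scores
#' \deqn{u_i = (Y_i - \hat\tau_0 Z_i - \hat\mu^*_i)(Z_i - \hat e_i)
#'        - (\hat\tau^* - \hat\tau_0)\, w_i, \qquad w_i = (Z_i - \hat e_i)^2,}
#' which sum to zero exactly by the definition of the global revised estimate
#' \eqn{\hat\tau^*}. The variance estimate is
#' \eqn{\hat\sigma^2 = n^{-1}\sum_i u_i^2 / w_i} and the studentized scores
#' are \eqn{s_i = u_i / (\hat\sigma \sqrt{w_i})}, marginally approximately
#' standard normal under the null of no heterogeneity; they satisfy
#' \eqn{a^\top s = 0} with \eqn{a = (\sqrt{w_1}, \ldots, \sqrt{w_n})}.
#'
#' @inheritParams estimate_tau_star_global
#' @param tau_star_global Bias-corrected global effect
#'   [estimate_tau_star_global()].
#' @return List with `u`, `s`, `w`, `sigma2_hat`.
#' @export
compute_scores <- function(Y, Z, e_hat, mu_star_hat, tau0, tau_star_global) {
  w <- (Z - e_hat)^2
  if (any(w <= 0)) stop("degenerate weights: some (Z - e_hat)^2 are zero",
                        call. = FALSE)
  u <- (Y - tau0 * Z - mu_star_hat) * (Z - e_hat) - (tau_star_global - tau0) * w
  sigma2 <- mean(u^2 / w)
  if (sigma2 <= 0) stop("degenerate residuals: sigma2_hat is zero", call. = FALSE)
  list(u = u, s = u / (sqrt(sigma2) * sqrt(w)), w = w, sigma2_hat = sigma2)
}

#' Projection onto the orthogonal complement of a vector
#'
#' \eqn{P = I - a a^\top / (a^\top a)}: symmetric, idempotent, annihilates
#' `a`, rank \eqn{n - 1}.
#'
#' @param a Nonzero numeric vector.
#' @return n x n projection matrix.
#' @export
projection_matrix <- function(a) {
  c2 <- sum(a^2)
  if (c2 == 0) stop("projection direction is the zero vector", call. = FALSE)
  diag(length(a)) - tcrossprod(a) / c2
}

#' Gaussian radial-basis-function kernel matrix
#'
#' \eqn{K_{ij} = \exp\{-\lVert x_i - x_j \rVert^2 / (2h^2)\}} on
#' column-standardized covariates. The default bandwidth is the median
#' heuristic: `h` is the median pairwise Euclidean distance between the
#' standardized rows.
#'
#' @param X Covariate matrix.
#' @param bandwidth Positive bandwidth `h`, or `"median"` for the median
#'   heuristic.
#' @param standardize Standardize columns before computing distances.
#' @return Symmetric positive-semidefinite n x n matrix with unit diagonal.
#' @export
rbf_kernel_matrix <- function(X, bandwidth = "median", standardize = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("covariates contain non-finite values", call. = FALSE)
  if (standardize) {
    scl <- apply(X, 2, stats::sd); scl[scl < 1e-12] <- 1
    X <- sweep(sweep(X, 2, colMeans(X)), 2, scl, "/")
  }
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  if (identical(bandwidth, "median")) {
    h <- sqrt(stats::median(D2[upper.tri(D2)]))
    if (!is.finite(h) || h <= 0) h <- 1
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    h <- bandwidth
  }
  K <- exp(-D2 / (2 * h^2))
  attr(K, "bandwidth") <- h
  K
}

# nonzero eigenvalues of P K P without forming P explicitly
pkp_eigenvalues <- function(Kmat, a, eig_tol = 1e-8) {
  c2 <- sum(a^2)
  Ka <- as.vector(Kmat %*% a)
  M <- Kmat - outer(a, Ka) / c2 - outer(Ka, a) / c2 +
    (sum(a * Ka) / c2^2) * tcrossprod(a)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(lam, 0)
  if (lmax <= 0) return(numeric(0))
  if (min(lam) < -1e-6 * lmax)
    warning("projected kernel has a nontrivially negative eigenvalue")
  lam[lam > eig_tol * lmax]
}

#' Tail probability of a positively weighted chi-square mixture
#'
#' Computes \eqn{\Pr\{\sum_j \lambda_j \chi^2_{1,j} \ge Q\}} by numerical
#' inversion of the characteristic function (Imhof's integral, evaluated with
#' adaptive quadrature to absolute accuracy `acc`), the analytic null
#' distribution of the kernel score statistic. If the inversion fails or
#' returns a value outside \eqn{[0, 1]} beyond tolerance, a moment-matching
#' (Liu-type) approximation is used and flagged in the `"method"` attribute.
#'
#' @param Q Observed statistic, `>= 0`.
#' @param lambdas Mixture weights; must be positive up to a small relative
#'   tolerance (tiny negatives are dropped).
#' @param acc Target absolute accuracy of the inversion.
#' @return p-value in `[0, 1]`, with attribute `method` equal to
#'   `"inversion"` or `"moment"`.
#' @export
davies_pvalue <- function(Q, lambdas, acc = 1e-6) {
  stopifnot(Q >= 0, length(lambdas) >= 1)
  lmax <- max(lambdas)
  if (lmax <= 0) stop("no positive mixture weights", call. = FALSE)
  if (min(lambdas) < -1e-6 * lmax)
    stop("negative mixture weight beyond tolerance", call. = FALSE)
  lambdas <- lambdas[lambdas > 0]
  if (Q == 0) return(structure(1, method = "inversion"))

  imhof_integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * Q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambdas^2, u^2))))
    sin(theta) / (u * rho)
  }
  p <- tryCatch({
    val <- stats::integrate(imhof_integrand, 0, Inf, abs.tol = acc,
                            rel.tol = acc, subdivisions = 2000L)$value
    0.5 + val / pi
  }, error = function(e) NA_real_)
  if (is.finite(p) && p > -1e-4 && p < 1 + 1e-4) {
    return(structure(min(max(p, 0), 1), method = "inversion"))
  }
  structure(liu_pvalue(Q, lambdas), method = "moment")
}

# Liu-Tang-Zhang moment-matched noncentral chi-square approximation
liu_pvalue <- function(Q, lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  t_star <- (Q - c1) / sqrt(2 * c2)
  stats::pchisq(t_star * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}

#' Kernel score test for treatment-effect heterogeneity
#'
#' Tests \eqn{H_0 : \mathrm{Var}\{\tau(X)\} = 0}. The studentized residual
#' scores `s` (see [compute_scores()]) are projected onto the orthogonal
#' complement of the constraint direction \eqn{a = \sqrt{w}},
#' \eqn{\tilde s = P s}, and the quadratic form
#' \eqn{Q = \tilde s^\top K \tilde s} is referred to its analytic null law,
#' the mixture \eqn{\sum_j \lambda_j \chi^2_{1,j}} with \eqn{\lambda_j} the
#' nonzero eigenvalues of \eqn{P K P}.
#'
#' The `"revised"` variant builds scores from the centered outcome
#' regression \eqn{\hat\mu^*} and the bias-corrected global effect; the
#' `"unrevised"` variant builds them directly from \eqn{\hat\mu} and
#' \eqn{\hat\tau_0} (equivalent to substituting
#' \eqn{(\hat\tau_0, \hat\mu^*, \hat\tau^*) \to (0, \hat\mu, \hat\tau_0)}).
#'
#' @param data An `hte_data` object (or list with `X`, `Z`, `Y`).
#' @param nuisances A [cross_fit()] result with `e_hat` and `mu_hat`.
#' @param variant `"revised"` or `"unrevised"`.
#' @param fit Optional `hte_fit` from [fit_revised()] whose `mu_star_hat` is
#'   reused; otherwise the revised variant cross-fits the centered outcome
#'   regression itself with the learner stored in `nuisances`.
#' @param bandwidth RBF bandwidth, see [rbf_kernel_matrix()].
#' @param eig_tol Relative eigenvalue truncation threshold.
#' @param kernel_matrix,lambdas Optional precomputed kernel matrix and
#'   eigenvalues of \eqn{PKP} (they depend only on `X` and the propensity,
#'   so they can be shared between the two variants).
#' @param seed Seed for the internal centered-regression cross-fit.
#' @return An object of class `kernel_score_result`: list with `u`, `s`,
#'   `w`, `sigma2_hat`, `Q`, `lambdas`, `p_value`, `k_eff`
#'   (\eqn{(\sum\lambda)^2/\sum\lambda^2}), `variant`, `bandwidth`,
#'   `p_method`.
#' @export
kernel_score_test <- function(data, nuisances,
                              variant = c("revised", "unrevised"),
                              fit = NULL, bandwidth = "median",
                              eig_tol = 1e-8, kernel_matrix = NULL,
                              lambdas = NULL, seed = 1L) {
  variant <- match.arg(variant)
  X <- as.matrix(data$X); Z <- data$Z; Y <- data$Y
  e_hat <- nuisances$e_hat; mu_hat <- nuisances$mu_hat
  stopifnot(!is.null(e_hat), !is.null(mu_hat))

  tau0 <- estimate_tau0(Y, Z, mu_hat, e_hat)
  if (variant == "revised") {
    mu_star_hat <- fit$mu_star_hat
    if (is.null(mu_star_hat)) {
      Y_star <- center_outcome(Y, Z, tau0)
      mu_star_hat <- cross_fit_target(X, Y_star, "regression",
                                      nuisances$fold_of, nuisances$learner,
                                      seed = seed + 201L)$pred
    }
    tau_star_global <- estimate_tau_star_global(Y, Z, mu_star_hat, e_hat, tau0)
    sc <- compute_scores(Y, Z, e_hat, mu_star_hat, tau0, tau_star_global)
  } else {
    sc <- compute_scores(Y, Z, e_hat, mu_hat, tau0 = 0,
                         tau_star_global = tau0)
  }

  a <- sqrt(sc$w)
  if (is.null(kernel_matrix))
    kernel_matrix <- rbf_kernel_matrix(X, bandwidth = bandwidth)
  if (is.null(lambdas))
    lambdas <- pkp_eigenvalues(kernel_matrix, a, eig_tol = eig_tol)

  s_tilde <- sc$s - a * sum(a * sc$s) / sum(a^2)
  Q <- as.numeric(s_tilde %*% kernel_matrix %*% s_tilde)
  Q <- max(Q, 0)

  if (length(lambdas) == 0) {
    warning("all eigenvalues of the projected kernel are below tolerance; p = 1")
    p <- structure(1, method = "degenerate")
    k_eff <- 0
  } else {
    p <- davies_pvalue(Q, lambdas)
    k_eff <- sum(lambdas)^2 / sum(lambdas^2)
  }
  out <- list(u = sc$u, s = sc$s, w = sc$w, sigma2_hat = sc$sigma2_hat,
              Q = Q, lambdas = lambdas, p_value = as.numeric(p),
              p_method = attr(p, "method"), k_eff = k_eff,
              variant = variant,
              bandwidth = attr(kernel_matrix, "bandwidth") %||% bandwidth)
  class(out) <- "kernel_score_result"
  out
}

#' @export
print.kernel_score_result <- function(x, ...) {
  cat(sprintf("kernel score test (%s): Q = %.4g, k_eff = %.1f, p = %.4g\n",
              x$variant, x$Q, x$k_eff, x$p_value))
  invisible(x)
}
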