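#' True propensity score of the built-in simulation design
#'
#' Treatment assignment probability used by [simulate_hte()]:
#' \eqn{e(x) = \mathrm{logit}^{-1}\{0.8\sin(\pi x_1 x_2) + 0.6 x_3 x_4 +
#' 0.5\tanh(x_5)\}}. Only the first five covariates enter; the argument is
#' symmetric in distribution about 0 so the marginal treated fraction is 1/2
#' under standard-normal covariates.
#'
#' @param x Numeric vector of length >= 5, or a matrix with >= 5 columns
#'   (one row per subject).
#' @return Propensity value(s), strictly inside (0, 1).
#' @export
#' @examples
#' true_propensity(rep(0, 5)) # 0.5
true_propensity <- function(x) {
  x <- as_covariate_matrix(x)
  eta <- 0.8 * sin(pi * x[, 1] * x[, 2]) + 0.6 * x[, 3] * x[, 4] + 0.5 * tanh(x[, 5])
  stats::plogis(eta)
}

#' True outcome nuisance function of the built-in simulation design
#'
#' Baseline outcome surface \eqn{f(x) = \log(|x_1|+1) - x_2^2 + \sin(x_3) +
#' 0.5 x_4 x_5}, a nonlinear, nonadditive confounding structure. The absolute
#' value in the first term keeps \eqn{f} defined for all real \eqn{x_1}.
#'
#' @inheritParams true_propensity
#' @return Numeric value(s).
#' @export
true_f <- function(x) {
  x <- as_covariate_matrix(x)
  log(abs(x[, 1]) + 1) - x[, 2]^2 + sin(x[, 3]) + 0.5 * x[, 4] * x[, 5]
}

#' True treatment-effect function of the built-in simulation design
#'
#' The four effect scenarios:
#' \describe{
#'   \item{`"zero"`}{\eqn{\tau(x) = 0} (no effect, no heterogeneity).}
#'   \item{`"constant3"`}{\eqn{\tau(x) = 3} (large homogeneous effect).}
#'   \item{`"simple_hte"`}{\eqn{\tau(x) = -1 + 2\log\{\exp(\sum_{j=1}^5 x_j) + 1\}},
#'     a softplus of the first five covariates; strong heterogeneity
#'     (population variance about 6.05 under standard-normal covariates).}
#'   \item{`"complex_hte"`}{\eqn{\tau(x) = -1 + x_1 x_2 + \cos(2 x_3) +
#'     \max(x_4 - x_5, 0)}, weaker and nonsmooth heterogeneity.}
#' }
#'
#' @inheritParams true_propensity
#' @param scenario One of `"zero"`, `"constant3"`, `"simple_hte"`,
#'   `"complex_hte"`.
#' @return Numeric value(s).
#' @export
true_tau <- function(x, scenario = c("zero", "constant3", "simple_hte", "complex_hte")) {
  scenario <- match.arg(scenario)
  x <- as_covariate_matrix(x)
  switch(scenario,
    zero = rep(0, nrow(x)),
    constant3 = rep(3, nrow(x)),
    simple_hte = -1 + 2 * log1p(exp(rowSums(x[, 1:5, drop = FALSE]))),
    complex_hte = -1 + x[, 1] * x[, 2] + cos(2 * x[, 3]) +
      pmax(x[, 4] - x[, 5], 0)
  )
}

as_covariate_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) < 5) {
    stop("covariate vector must have at least 5 entries (x1..x5 enter the design)",
         call. = FALSE)
  }
  x
}

#' Simulate an observational dataset with confounded treatment assignment
#'
#' Draws covariates \eqn{X_i \sim N_p(0, I_p)}, treatment
#' \eqn{Z_i \sim \mathrm{Bernoulli}\{e(X_i)\}} with the nonlinear propensity
#' [true_propensity()], and outcome
#' \eqn{Y_i = \tau(X_i) Z_i + f(X_i) + \varepsilon_i},
#' \eqn{\varepsilon_i \sim N(0, \sigma^2)}. The true per-subject
#' \eqn{e(X_i)}, \eqn{f(X_i)} and \eqn{\tau(X_i)} are stored alongside the
#' data so that oracle checks never have to re-derive them.
#'
#' Covariates, treatment and noise are drawn in that fixed order from a single
#' RNG stream, so a given `seed` reproduces the dataset bit-for-bit.
#'
#' @param n Sample size (0 gives an empty dataset).
#' @param p Covariate dimension, at least 5.
#' @param sigma Noise standard deviation (> 0).
#' @param tau_scenario Effect scenario, see [true_tau()].
#' @param seed Integer RNG seed.
#' @return An object of class `hte_data`: a list with matrix `X` (n x p),
#'   integer vector `Z`, numeric vector `Y`, and list `truth` with elements
#'   `e`, `f`, `tau`.
#' @export
#' @examples
#' d <- simulate_hte(200, p = 5, sigma = 1, tau_scenario = "simple_hte", seed = 1)
#' mean(d$Z)
simulate_hte <- function(n, p = 20, sigma = 1,
                         tau_scenario = c("zero", "constant3", "simple_hte", "complex_hte"),
                         seed = 1L) {
  tau_scenario <- match.arg(tau_scenario)
  stopifnot(n >= 0, p >= 5, sigma > 0)
  if (n == 0) {
    out <- list(X = matrix(numeric(0), 0, p), Z = integer(0), Y = numeric(0),
                truth = list(e = numeric(0), f = numeric(0), tau = numeric(0)),
                sigma = sigma, tau_scenario = tau_scenario, seed = seed)
    class(out) <- "hte_data"
    return(out)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- paste0("X", seq_len(p))
  e <- true_propensity(X)
  Z <- stats::rbinom(n, 1L, e)
  f <- true_f(X)
  tau <- true_tau(X, tau_scenario)
  Y <- tau * Z + f + stats::rnorm(n, 0, sigma)
  out <- list(X = X, Z = Z, Y = Y, truth = list(e = e, f = f, tau = tau),
              sigma = sigma, tau_scenario = tau_scenario, seed = seed)
  class(out) <- "hte_data"
  out
}

#' @export
print.hte_data <- function(x, ...) {
  cat(sprintf("hte_data: n = %d, p = %d, scenario = %s, treated = %d\n",
              length(x$Y), ncol(x$X), x$tau_scenario, sum(x$Z)))
  invisible(x)
}

#' Write / read an observational dataset as delimited text
#'
#' Column layout is `Y, Z, X1..Xp` with optional truth columns
#' `e_true, f_true, tau_true` appended when present.
#'
#' @param data An `hte_data` object (or any list with `Y`, `Z`, `X`).
#' @param path File path.
#' @param truth Whether to include the truth columns (writer only; ignored
#'   when the dataset carries none).
#' @return `read_hte_csv()` returns an `hte_data` object (with `truth` only
#'   if the file has the truth columns); `write_hte_csv()` returns `path`
#'   invisibly.
#' @export
write_hte_csv <- function(data, path, truth = TRUE) {
  df <- data.frame(Y = data$Y, Z = data$Z)
  X <- as.matrix(data$X)
  colnames(X) <- paste0("X", seq_len(ncol(X)))
  df <- cbind(df, as.data.frame(X))
  if (truth && !is.null(data$truth) && length(data$truth$e) == length(data$Y)) {
    df$e_true <- data$truth$e
    df$f_true <- data$truth$f
    df$tau_true <- data$truth$tau
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hte_csv
#' @export
read_hte_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("Y", "Z") %in% names(df)))
  xcols <- grep("^X[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^X", "", xcols)))]
  X <- as.matrix(df[, xcols, drop = FALSE])
  out <- list(X = X, Z = as.integer(df$Z), Y = as.numeric(df$Y), truth = NULL)
  if (all(c("e_true", "f_true", "tau_true") %in% names(df))) {
    out$truth <- list(e = df$e_true, f = df$f_true, tau = df$tau_true)
  }
  class(out) <- "hte_data"
  out
}

# save/restore the global RNG state so simulators don't disturb callers
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
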