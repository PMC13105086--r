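#' Simulation grid for testing / estimation experiments
#'
#' Expands the supplied parameter vectors into one row per configuration
#' cell, for use with [run_test_experiment()] and
#' [run_estimation_experiment()].
#'
#' @param n,p,sigma,tau_scenario Vectors of design values (crossed).
#' @return Data frame of cells.
#' @export
experiment_grid <- function(n = 1000, p = 20, sigma = 1,
                            tau_scenario = "zero") {
  expand.grid(n = n, p = p, sigma = sigma, tau_scenario = tau_scenario,
              stringsAsFactors = FALSE)
}

#' Rejection-rate experiment (Type I error / power)
#'
#' For every cell and replicate: simulate a dataset, run the full pipeline
#' ([hte_analysis()]) and record whether each requested test rejects at
#' level `alpha`. Aggregates empirical rejection rates with binomial
#' Monte-Carlo standard errors. Replicate failures are caught, counted and
#' excluded (never silently dropped).
#'
#' @param grid Data frame of cells from [experiment_grid()].
#' @param replicates Replicates per cell.
#' @param variants,tests,B,K,learner,bandwidth Passed to [hte_analysis()].
#' @param alpha Nominal level.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param verbose Print per-cell progress to stderr.
#' @return An object of class `hte_experiment`: list with `report` (one row
#'   per cell x variant x test: rejection rate, standard error, failures)
#'   and `records` (per-replicate p-values).
#' @export
run_test_experiment <- function(grid, replicates = 100,
                                variants = "revised", tests = "analytic",
                                B = 499, K = 5,
                                learner = learner_bagged_mlp(),
                                bandwidth = "median", alpha = 0.05,
                                seed = 1L, verbose = FALSE) {
  stopifnot(replicates >= 1, alpha > 0, alpha < 1)
  seeds <- derive_seeds(seed, nrow(grid) * replicates)
  records <- list()
  n_fail <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    if (verbose)
      message(sprintf("cell %d/%d: n=%d p=%d sigma=%g scenario=%s",
                      g, nrow(grid), cell$n, cell$p, cell$sigma,
                      cell$tau_scenario))
    for (r in seq_len(replicates)) {
      sr <- seeds[(g - 1) * replicates + r]
      rec <- tryCatch({
        d <- simulate_hte(cell$n, cell$p, cell$sigma, cell$tau_scenario,
                          seed = sr)
        res <- hte_analysis(d, K = K, learner = learner, variants = variants,
                            tests = tests, B = B, bandwidth = bandwidth,
                            seed = sr)
        pv <- list()
        for (v in names(res$analytic))
          pv[[length(pv) + 1]] <- data.frame(test = "analytic", variant = v,
                                             p_value = res$analytic[[v]]$p_value)
        for (v in names(res$permutation))
          pv[[length(pv) + 1]] <- data.frame(test = "permutation", variant = v,
                                             p_value = res$permutation[[v]]$p_value)
        cbind(cell, replicate = r, do.call(rbind, pv), row.names = NULL)
      }, error = function(e) {
        warning(sprintf("replicate %d of cell %d failed: %s", r, g,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(rec)) n_fail[g] <- n_fail[g] + 1L else
        records[[length(records) + 1]] <- rec
    }
  }
  records <- do.call(rbind, records)
  key <- interaction(records$n, records$p, records$sigma,
                     records$tau_scenario, records$test, records$variant,
                     drop = TRUE)
  agg <- lapply(split(records, key), function(df) {
    rate <- mean(df$p_value < alpha)
    R <- nrow(df)
    data.frame(n = df$n[1], p = df$p[1], sigma = df$sigma[1],
               tau_scenario = df$tau_scenario[1], test = df$test[1],
               variant = df$variant[1], replicates = R,
               rejection_rate = rate, se = sqrt(rate * (1 - rate) / R))
  })
  report <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out <- list(report = report, records = records, n_fail = n_fail,
              alpha = alpha, seed = seed)
  class(out) <- "hte_experiment"
  out
}

#' Estimation-accuracy experiment (held-out log-MSE)
#'
#' For every cell and replicate: simulate a training set and an independent
#' test set of equal size, fit both the unrevised and the revised estimator,
#' and record the held-out log mean squared error of the effect predictions
#' against the stored truth.
#'
#' @inheritParams run_test_experiment
#' @return An `hte_experiment` with mean log-MSE per cell and variant.
#' @export
run_estimation_experiment <- function(grid, replicates = 10, K = 5,
                                      learner = learner_bagged_mlp(),
                                      seed = 1L, verbose = FALSE) {
  stopifnot(replicates >= 1)
  seeds <- derive_seeds(seed, nrow(grid) * replicates * 2)
  records <- list()
  n_fail <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    if (verbose)
      message(sprintf("cell %d/%d: n=%d p=%d sigma=%g scenario=%s",
                      g, nrow(grid), cell$n, cell$p, cell$sigma,
                      cell$tau_scenario))
    for (r in seq_len(replicates)) {
      i0 <- 2 * ((g - 1) * replicates + r - 1)
      rec <- tryCatch({
        train <- simulate_hte(cell$n, cell$p, cell$sigma, cell$tau_scenario,
                              seed = seeds[i0 + 1])
        test <- simulate_hte(cell$n, cell$p, cell$sigma, cell$tau_scenario,
                             seed = seeds[i0 + 2])
        nuis <- cross_fit(train, c("e", "mu"), K = K, learner = learner,
                          seed = seeds[i0 + 1])
        fu <- fit_r_learner(train, nuis, keep_models = TRUE,
                            seed = seeds[i0 + 1])
        fr <- fit_revised(train, nuis, keep_models = TRUE,
                          seed = seeds[i0 + 1])
        data.frame(cell, replicate = r,
                   variant = c("unrevised", "revised"),
                   log_mse = c(log_mse(predict(fu, test$X), test$truth$tau),
                               log_mse(predict(fr, test$X), test$truth$tau)),
                   row.names = NULL)
      }, error = function(e) {
        warning(sprintf("replicate %d of cell %d failed: %s", r, g,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(rec)) n_fail[g] <- n_fail[g] + 1L else
        records[[length(records) + 1]] <- rec
    }
  }
  records <- do.call(rbind, records)
  key <- interaction(records$n, records$p, records$sigma,
                     records$tau_scenario, records$variant, drop = TRUE)
  agg <- lapply(split(records, key), function(df) {
    data.frame(n = df$n[1], p = df$p[1], sigma = df$sigma[1],
               tau_scenario = df$tau_scenario[1], variant = df$variant[1],
               replicates = nrow(df), mean_log_mse = mean(df$log_mse),
               se = stats::sd(df$log_mse) / sqrt(nrow(df)))
  })
  report <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out <- list(report = report, records = records, n_fail = n_fail,
              seed = seed)
  class(out) <- "hte_experiment"
  out
}

#' @export
print.hte_experiment <- function(x, ...) {
  print(x$report)
  if (sum(x$n_fail) > 0)
    cat(sprintf("(%d replicate(s) failed and were excluded)\n", sum(x$n_fail)))
  invisible(x)
}

#' Group average treatment effect
#'
#' Mean of the individual effect predictions over a subgroup.
#'
#' @param tau_star Vector of individual effect estimates.
#' @param group_mask Logical vector (or index vector) selecting the
#'   subgroup; must select at least one subject.
#' @return Scalar GATE.
#' @export
group_average_effect <- function(tau_star, group_mask) {
  if (is.logical(group_mask)) {
    stopifnot(length(group_mask) == length(tau_star))
    if (!any(group_mask)) stop("empty subgroup", call. = FALSE)
    return(mean(tau_star[group_mask]))
  }
  if (length(group_mask) == 0) stop("empty subgroup", call. = FALSE)
  mean(tau_star[group_mask])
}

# fan a master seed out to independent 31-bit replicate seeds
derive_seeds <- function(seed, m) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, m)
}
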