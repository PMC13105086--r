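# Reduced-size learners used throughout the test suite: small networks and
# few bags keep each fit fast while exercising the full bagging/cross-fitting
# machinery. Statistical checks that depend on learner quality use the
# problem sizes documented in the methods vignette.

fast_control <- function(epochs = 60) {
  mlp_control(hidden = c(16, 8), epochs = epochs, batch = 128, patience = 10)
}

fast_mlp_learner <- function(n_bags = 3) {
  learner_bagged_mlp(n_bags = n_bags, control = fast_control())
}

# ensemble scale used for the calibration/power reproductions: mid-size
# networks, 10 members for the (noisier) propensity task, 5 for regressions
calib_control <- function() {
  mlp_control(hidden = c(32, 16), epochs = 150, batch = 128, lr = 0.003,
              patience = 15)
}

calib_mlp_learner <- function() {
  learner_bagged_mlp(n_bags = 5, n_bags_binary = 10,
                     control = calib_control())
}

ridge_learner <- function() learner_ridge()

# manual nuisance container built from stored simulation truth, for oracle
# checks that bypass learner fitting entirely
truth_nuisances <- function(data, K = 5, seed = 1L) {
  mu <- data$truth$tau * data$truth$e + data$truth$f  # E[Y|X] = tau*e + f
  structure(list(fold_of = make_folds(length(data$Y), K, seed = seed,
                                      stratify = data$Z),
                 e_hat = data$truth$e, mu_hat = mu, K = K,
                 learner = learner_ridge(), clip_lo = 0.01,
                 seed = as.integer(seed), models = list()),
            class = "crossfit_nuisances")
}
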