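# htelearn

Estimation and testing of heterogeneous treatment effects (HTE) from
observational data with a continuous outcome, a binary treatment and
tabular covariates — for biostatisticians analysing registry-style cohorts
where treatment assignment is confounded by many interacting patient
characteristics (the motivating setting is comparing bilateral versus
single lung transplantation on post-transplant lung function).

## What it does

Data are modelled as partially linear,

    Y = tau(X) Z + f(X) + eps,   E[eps | X, Z] = 0,

with both the effect surface `tau(X)` and the confounding surface `f(X)`
unspecified. The package provides:

* **Cross-fitted nuisance estimation** of `e(X) = E[Z|X]` and
  `mu(X) = E[Y|X]` with bagged neural networks (compiled multilayer
  perceptrons, bootstrap-aggregated with out-of-bag filtering of poorly
  performing members), so every nuisance prediction is strictly
  out-of-fold.
* **R-learner estimation** of `tau(X)` via the Robinson transformation,
  plus a **revised (centered) estimator**: estimate the constant effect
  `tau0` by the doubly robust ratio, center the outcome `Y* = Y - tau0 Z`,
  re-fit the outcome regression on `Y*`, and estimate only the residual
  heterogeneity `r(X)`, returning `tau*(X) = tau0 + r(X)`. Centering
  removes the residual bimodality that a large treatment effect induces,
  which otherwise biases the outcome regression and everything downstream.
* **A global test of `H0: Var{tau(X)} = 0`** in two forms: an analytic
  kernel score test — studentized residual scores projected off the
  constraint direction, quadratic form in an RBF kernel, p-value from the
  chi-square-mixture null via characteristic-function inversion — and a
  cross-fitted permutation test that shuffles out-of-fold effect
  predictions within (fold, arm) cells.
* **A simulator** of registry-like confounded data (nonlinear propensity
  and outcome surfaces, four effect scenarios) and **experiment drivers**
  for Type I error, power and held-out log-MSE grids, plus group average
  treatment effects (GATE).

## Worked example

```r
library(htelearn)

# simulated cohort: n = 1000, 20 covariates, complex heterogeneous effect
d <- simulate_hte(1000, p = 20, sigma = 1, tau_scenario = "complex_hte",
                  seed = 1)

res <- hte_analysis(d, K = 5,
                    learner = learner_bagged_mlp(
                      n_bags = 5,
                      control = mlp_control(hidden = c(32, 16), epochs = 150,
                                            batch = 128, lr = 0.003,
                                            patience = 15)),
                    variants = "revised", tests = c("analytic", "permutation"),
                    B = 499, seed = 1)
print(res)
#> analytic  revised   p = 0.003987 (Q = 1.1e+03, k_eff = 19.9)
#> permutation revised   p = 0.002 (B = 499)
```

Both tests reject: the effect surface really is heterogeneous in this
scenario. The fitted effects and subgroup summaries:

```r
fit <- res$fits$revised
print(fit)
#> hte_fit (revised): tau0 = -0.3381, tau_star_global = -0.2096, sd(tau_star) = 1.4445
group_average_effect(fit$tau_star, d$X[, 1] > 0)   # GATE, X1-defined subgroup
#> [1] -0.3255135
group_average_effect(fit$tau_star, d$X[, 1] <= 0)
#> [1] -0.08673802
cor(fit$tau_star, d$truth$tau)                     # truth stored by simulator
#> [1] 0.4024261
```

`tau0` is the constant-effect component (the population mean of `tau(X)`
is about -0.30 in this scenario), `sd(tau_star)` the spread of the
estimated individual effects, and `k_eff` the moment-matched effective
degrees of freedom of the detected heterogeneity. The out-of-fold
correlation with the stored truth is about 0.40 at this deliberately
small ensemble; the package default (`n_bags = 20`) and larger samples
raise it. Under the null scenario (`tau_scenario = "zero"`) the same
pipeline gives unremarkable p-values, e.g. `p = 0.34` for the analytic
test at `seed = 3`.

A command-line interface wrapping the same functions ships in
`inst/cli/htelearn` (subcommands `simulate`, `fit`, `test`,
`experiment`).

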