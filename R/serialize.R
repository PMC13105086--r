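#' Save / load a fitted effect model as a JSON bundle
#'
#' Serializes an `hte_fit` — including the per-fold effect ensembles when
#' the fit was run with `keep_models = TRUE` — to a single JSON file at full
#' numeric precision, so fitted models can be archived or moved between
#' sessions as plain text. Ridge and bagged-network fold models are both
#' supported.
#'
#' @param fit An `hte_fit` object.
#' @param path File path for the JSON bundle.
#' @return `save_hte_fit()` returns `path` invisibly; `load_hte_fit()`
#'   returns the restored `hte_fit`.
#' @export
save_hte_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hte_fit"))
  payload <- list(
    variant = fit$variant, tau0 = fit$tau0,
    tau_star_global = fit$tau_star_global,
    tau_star = fit$tau_star, r_hat = fit$r_hat,
    mu_star_hat = fit$mu_star_hat, fold_of = fit$fold_of,
    models = lapply(fit$models, serialize_model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_hte_fit
#' @export
load_hte_fit <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  models <- if (length(p$models)) lapply(p$models, deserialize_model) else NULL
  out <- list(variant = p$variant, tau0 = p$tau0,
              tau_star_global = p$tau_star_global,
              tau_star = p$tau_star, r_hat = p$r_hat,
              mu_star_hat = p$mu_star_hat, fold_of = p$fold_of,
              models = models)
  class(out) <- "hte_fit"
  out
}

serialize_model <- function(m) {
  if (inherits(m, "bagged_mlp")) {
    list(type = "bagged_mlp", task = m$task, clip_lo = m$clip_lo,
         kept = m$kept, oob_loss = m$oob_loss, n_bags = m$n_bags,
         members = lapply(m$members, function(mm)
           list(W = mm$net$W, b = mm$net$b, task = mm$net$task,
                x_center = mm$x_center, x_scale = mm$x_scale,
                y_center = mm$y_center, y_scale = mm$y_scale,
                mlp_task = mm$task)))
  } else if (inherits(m, "htel_ridge")) {
    list(type = "ridge", task = m$task,
         beta = if (!is.null(m$beta)) as.numeric(m$beta),
         glm_coef = m$glm_coef, clip_lo = m$clip_lo,
         x_center = m$x_center, x_scale = m$x_scale)
  } else {
    stop("cannot serialize models of class ", paste(class(m), collapse = "/"),
         call. = FALSE)
  }
}

deserialize_model <- function(s) {
  if (s$type == "bagged_mlp") {
    members <- lapply(s$members, function(mm) {
      structure(list(net = list(W = lapply(mm$W, as.matrix),
                                b = lapply(mm$b, as.numeric),
                                task = mm$task),
                     x_center = mm$x_center, x_scale = mm$x_scale,
                     y_center = mm$y_center, y_scale = mm$y_scale,
                     task = mm$mlp_task),
                class = "htel_mlp")
    })
    structure(list(members = members, kept = s$kept, oob_loss = s$oob_loss,
                   task = s$task, clip_lo = s$clip_lo, n_bags = s$n_bags),
              class = "bagged_mlp")
  } else if (s$type == "ridge") {
    obj <- list(task = s$task, x_center = s$x_center, x_scale = s$x_scale,
                clip_lo = s$clip_lo)
    if (!is.null(s$beta)) obj$beta <- matrix(s$beta, ncol = 1)
    if (!is.null(s$glm_coef)) obj$glm_coef <- unlist(s$glm_coef)
    structure(obj, class = "htel_ridge")
  } else {
    stop("unknown serialized model type: ", s$type, call. = FALSE)
  }
}
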