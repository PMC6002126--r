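#' Tidy and glance methods
#'
#' Broom-style summaries for fitted objects: `tidy()` returns one row per
#' parameter, `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name dispersim-tidiers
NULL

#' @rdname dispersim-tidiers
#' @export
tidy.estimator_fit <- function(x, ...) {
  co <- c(x$beta, x$theta)
  out <- tibble(term = names(co), estimate = unname(co))
  if (!is.null(x$omega_normalized)) {
    out <- bind_rows(out, tibble(
      term = paste0("w", seq_along(x$omega_normalized), "_normalized"),
      estimate = unname(x$omega_normalized)))
  }
  out
}

#' @rdname dispersim-tidiers
#' @export
glance.estimator_fit <- function(x, ...) {
  tibble(model_id = x$model_id, logLik = x$train_ll, n_train = x$n_train,
         n_params = length(x$beta) + length(x$theta) -
           ("beta1" %in% names(x$beta) && x$beta[["beta1"]] == 1 &&
              x$model_id == "wgt"))
}

#' @rdname dispersim-tidiers
#' @export
tidy.gpr_fit <- function(x, ...) {
  tibble(term = c("theta", paste0("sigma", seq_along(x$hp$sigma)), "sigma_I"),
         estimate = c(x$hp$theta, x$hp$sigma, x$hp$sigma_I))
}

#' @rdname dispersim-tidiers
#' @export
glance.gpr_fit <- function(x, ...) {
  tibble(model_id = "gpr", inner_cv_loglik = x$inner_objective,
         n_train = x$n_train)
}

#' @rdname dispersim-tidiers
#' @export
tidy.dirichlet_posterior <- function(x, ...) {
  tibble(model_id = x$models, alpha = unname(x$alpha), r = unname(x$r),
         p_exc = unname(exceedance_probability(x)))
}

#' @rdname dispersim-tidiers
#' @export
glance.dirichlet_posterior <- function(x, ...) {
  tibble(n_participants = x$n_participants, n_models = length(x$alpha),
         alpha_sum = sum(x$alpha))
}
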