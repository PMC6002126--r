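#' Default generating parameters for synthetic participants
#'
#' Plausible parameter sets per generating model, used by
#' [simulate_participant()] when `params` is not given. Mapping intercepts
#' and slopes are in the range observed for compliant human-scale behaviour
#' (responses roughly proportional to the sample dispersion with a mild bias
#' toward intermediate values); the KDE width factor matches wide, strongly
#' overlapping kernels and the weighting pattern emphasizes the third
#' excentricity rank.
#'
#' @param model_id Generating model identifier.
#' @return Named list of true parameters.
#' @export
default_true_params <- function(model_id) {
  switch(model_id,
    nm = list(beta0 = 10, beta1 = 0.8),
    max = list(beta0 = 5, beta1 = 0.55),
    rng = list(beta0 = 5, beta1 = 0.3),
    wgt = list(beta0 = 8, omega = c(0.5, 1.0, 1.8, 0.7)),
    gnm = list(beta0 = 8, beta1 = 0.6, p = 1.2),
    kde = list(beta0 = 5, beta1 = 0.9, a = 0.5),
    delta_kde = list(beta0 = 5, beta1 = 1.0),
    tlg = list(beta0 = 10, beta1 = 0.9),
    benchmark = list(),
    abort(paste0("no default parameters for model: ", model_id))
  )
}

# noiseless model predictions for a session, given true parameters
true_predictions <- function(session, model_id, params) {
  if (model_id == "benchmark") {
    return(benchmark_response(session)$y_benchmark)
  }
  reg <- est_registry()[[model_id]]
  if (is.null(reg)) abort(paste0("unknown generating model: ", model_id))
  ctx <- estimator_context(session, train_mean_y = 0)
  theta <- if (reg$beta1_fixed) params$omega
  else unlist(params[reg$theta_names], use.names = FALSE)
  S <- reg$S_fun(ctx, theta)
  b1 <- if (reg$beta1_fixed) 1 else params$beta1
  apply_response_mapping(S, params$beta0, b1)
}

#' Simulate one synthetic participant
#'
#' Generates a session with the renormalized sampling scheme, computes
#' noiseless predictions from the generating model, and corrupts them with
#' heteroscedastic Gaussian response noise of SD
#' `theta(yhat) = noise[1] + noise[2] * yhat` (pixels), floored at zero
#' (frame widths are nonnegative). With probability `lapse_rate` a response
#' is replaced by a uniform draw over `lapse_range`. Benchmark feedback
#' (capture percentage, deviation score, 5-trial block averages) is attached
#' unless `feedback = FALSE`.
#'
#' The noise defaults (`theta = 2 + 0.10 * yhat` px, 2% lapses over
#' `[0, 300]` px) were calibrated once so that simulated cohorts show a
#' median absolute capture deviation near the ~6.5% seen in compliant human
#' observers, giving recovery analyses realistic difficulty.
#'
#' @param model_id Generating model (see [estimator_catalog()], plus
#'   `"benchmark"`).
#' @param params True parameters (default [default_true_params()]).
#' @param noise Length-2 affine noise profile `c(c0, c1)`.
#' @param lapse_rate Probability of a lapse trial, in `[0, 1)`.
#' @param lapse_range Support of the uniform lapse distribution (px).
#' @param n_trials Trials (default 320).
#' @param seed Master seed.
#' @param participant_id Identifier.
#' @param feedback Attach benchmark feedback columns (default TRUE).
#' @param config Optional [generator_config()].
#' @return A session tibble with responses `y`; the generating truth is in
#'   `attr(, "truth")`.
#' @export
simulate_participant <- function(model_id = "nm", params = NULL,
                                 noise = c(2, 0.10), lapse_rate = 0.02,
                                 lapse_range = c(0, 300), n_trials = 320,
                                 seed = NULL, participant_id = "p01",
                                 feedback = TRUE, config = NULL) {
  stopifnot(length(noise) == 2, lapse_rate >= 0, lapse_rate < 1)
  if (is.null(params)) params <- default_true_params(model_id)
  if (is.null(config)) config <- generator_config(n_trials = n_trials)
  session <- generate_session(config, seed = seed,
                              participant_id = participant_id)
  yhat <- true_predictions(session, model_id, params)
  if (any(noise[1] + noise[2] * yhat < 0))
    abort("noise profile yields negative SDs over the prediction range")
  y <- yhat + rnorm(length(yhat), 0, noise[1] + noise[2] * yhat)
  lapse <- runif(length(y)) < lapse_rate
  y[lapse] <- runif(sum(lapse), lapse_range[1], lapse_range[2])
  session$y <- pmax(y, 0)
  if (feedback) session <- add_feedback(session)
  attr(session, "truth") <- list(model_id = model_id, params = params,
                                 noise = noise, lapse_rate = lapse_rate,
                                 seed = seed)
  session
}

#' Simulate a cohort of synthetic participants
#'
#' Builds a complete cohort dataset plus a ground-truth manifest for recovery
#' scoring. The default cohort mirrors the study scale: 20 participants, 320
#' trials each, with a mix of generating models. Per-participant seeds are
#' derived deterministically from the master seed.
#'
#' @param configs Optional tibble with columns `participant_id`, `model_id`
#'   (and optionally a `params` list-column); defaults to a 20-participant
#'   mixed cohort.
#' @param n_trials Trials per participant.
#' @param seed Master seed.
#' @param feedback Attach benchmark feedback (slowest step; disable for
#'   quick checks).
#' @return List with `sessions` (one bound tibble) and `manifest` (tibble of
#'   generating truths).
#' @export
simulate_cohort <- function(configs = NULL, n_trials = 320, seed = 1,
                            feedback = TRUE) {
  if (is.null(configs)) configs <- default_cohort_configs()
  stopifnot(all(c("participant_id", "model_id") %in% names(configs)))
  sub <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L,
                                    nrow(configs)))
  out <- purrr::map(seq_len(nrow(configs)), function(i) {
    params <- if ("params" %in% names(configs) &&
                  !is.null(configs$params[[i]])) configs$params[[i]]
    else default_true_params(configs$model_id[i])
    simulate_participant(configs$model_id[i], params = params,
                         n_trials = n_trials, seed = sub[i],
                         participant_id = configs$participant_id[i],
                         feedback = feedback)
  })
  manifest <- tibble(
    participant_id = configs$participant_id,
    model_id = configs$model_id,
    seed = sub,
    params = purrr::map(out, ~ attr(.x, "truth")$params))
  list(sessions = bind_rows(out), manifest = manifest)
}

# 20 participants across the model zoo, weighted toward the instance-based
# generators that dominate human cohorts
default_cohort_configs <- function() {
  models <- c(rep("kde", 6), rep("wgt", 4), rep("nm", 4), rep("gnm", 2),
              rep("tlg", 2), "max", "delta_kde")
  tibble(participant_id = sprintf("p%02d", seq_along(models)),
         model_id = models)
}
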