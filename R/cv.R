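#' Stratified repeated cross-validation splits
#'
#' Assigns trials to `k`-fold splits such that the mean of the target variable
#' is approximately equal across folds: trials are first binned into the
#' 8-quantiles of the target distribution, slices are built containing one
#' trial per quantile, and whole slices are then sampled into folds. The
#' procedure is repeated `repeats` times with fresh randomization so that each
#' trial is held out once per repeat, giving `k * repeats` fold evaluations.
#'
#' @param y Target variable (responses), one per trial.
#' @param k Folds per repeat (default 5).
#' @param repeats Number of repeated splits (default 2 — ten evaluations).
#' @param n_strata Number of target quantile bins (default 8).
#' @param seed Seed for the fold randomization.
#' @return A tibble with columns `rep`, `fold`, `trial`.
#' @export
stratified_cv_splits <- function(y, k = 5, repeats = 2, n_strata = 8,
                                 seed = 1) {
  n <- length(y)
  if (n < n_strata * k) abort("too few trials for stratified splits")
  # equally filled quantile strata via ranks
  stratum <- ceiling(rank(y, ties.method = "first") / (n / n_strata))
  with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      # build slices: one randomly chosen member of each stratum per slice
      slice_id <- integer(n)
      for (s in unique(stratum)) {
        members <- sample(which(stratum == s))
        slice_id[members] <- seq_along(members)
      }
      # distribute whole slices over folds
      slices <- sort(unique(slice_id))
      fold_of_slice <- sample(rep(seq_len(k), length.out = length(slices)))
      tibble(rep = r, fold = fold_of_slice[match(slice_id, slices)],
             trial = seq_len(n))
    })
  })
}

#' Cross-validated log-likelihood of one model
#'
#' For every fold evaluation the model is fitted on the training folds only
#' (including its noise model), held-out responses are scored by the
#' lapse-mixture likelihood with bins assigned through the training-derived
#' edges, and the per-fold test log-likelihoods are summed. The CVLL is the
#' mean of these per-fold sums across all `k * repeats` evaluations, in
#' natural-log units.
#'
#' @param session Session tibble with responses.
#' @param model_id Model identifier (see [estimator_catalog()], plus
#'   `"gpr"`).
#' @param splits Fold assignments from [stratified_cv_splits()] (built from
#'   the session's responses if omitted).
#' @param control A [fit_control()].
#' @param seed Seed used when `splits` is omitted.
#' @return Scalar CVLL (mean per-fold held-out log-likelihood sum).
#' @export
cv_log_likelihood <- function(session, model_id, splits = NULL,
                              control = fit_control(), seed = 1) {
  if (is.null(splits)) splits <- stratified_cv_splits(session$y, seed = seed)
  folds <- dplyr::distinct(splits, .data$rep, .data$fold)
  per_fold <- purrr::pmap_dbl(folds, function(rep, fold) {
    test <- splits$trial[splits$rep == rep & splits$fold == fold]
    train <- setdiff(seq_len(nrow(session)), test)
    fit <- fit_estimator(session, model_id, control = control, idx = train)
    yhat <- predict(fit, session)
    response_loglik(session$y[test], yhat[test], fit$noise)
  })
  mean(per_fold)
}

#' Model evidence table for one or many participants
#'
#' Computes the CVLL of each candidate model, reusing identical fold
#' assignments per participant across models so that evidences are directly
#' comparable.
#'
#' @param session A session tibble; `cohort_evidence()` accepts a tibble
#'   holding several participants (split on `participant_id`).
#' @param models Character vector of model identifiers.
#' @param k,repeats,seed Passed to [stratified_cv_splits()].
#' @param control A [fit_control()].
#' @return A tibble with `participant_id`, `model_id`, `cvll`.
#' @export
cv_evidence <- function(session, models, k = 5, repeats = 2, seed = 1,
                        control = fit_control()) {
  splits <- stratified_cv_splits(session$y, k = k, repeats = repeats,
                                 seed = seed)
  tibble(participant_id = session$participant_id[1],
         model_id = models,
         cvll = vapply(models, function(m)
           cv_log_likelihood(session, m, splits, control), numeric(1)))
}

#' @rdname cv_evidence
#' @param cohort Tibble with several participants' sessions.
#' @export
cohort_evidence <- function(cohort, models, k = 5, repeats = 2, seed = 1,
                            control = fit_control()) {
  ids <- unique(cohort$participant_id)
  purrr::map_dfr(seq_along(ids), function(i) {
    cv_evidence(dplyr::filter(cohort, .data$participant_id == ids[i]),
                models, k = k, repeats = repeats, seed = seed + i,
                control = control)
  })
}

#' Evidence differences in decibans
#'
#' Converts a difference of natural-log evidences to decibans (decihartleys):
#' `10 * (a - b) / ln(10)`. Conventional reading: below 5 barely worth
#' mentioning, 5–10 substantial, 10–15 strong, 15–20 very strong, 20 and
#' above decisive.
#'
#' @param cvll_a,cvll_b Log evidences in natural-log units.
#' @export
dhart_diff <- function(cvll_a, cvll_b) 10 * (cvll_a - cvll_b) / log(10)

#' @rdname dhart_diff
#' @param delta Evidence difference in decibans.
#' @export
dhart_label <- function(delta) {
  cut(abs(delta), c(-Inf, 5, 10, 15, 20, Inf),
      labels = c("barely worth mentioning", "substantial", "strong",
                 "very strong", "decisive"), right = FALSE)
}

#' Permutation test for the weighting-model weights
#'
#' Tests each excentricity weight against the null that its input carries no
#' information: the tested input column (the excentricity-ranked offsets) is
#' permuted across trials, the weighting model is refitted (warm-started from
#' the observed fit), and the null distribution of the refitted `|omega_n|` is
#' compared with the observed value. One-sided p-values use the add-one
#' permutation estimator.
#'
#' @param session Session tibble with responses.
#' @param n_perm Number of permutations (default 10000; use fewer for quick
#'   checks — below 100 a warning flags unstable p-values).
#' @param alpha Significance threshold reported alongside.
#' @param control A [fit_control()].
#' @param seed Permutation seed.
#' @return Tibble with `weight`, `omega`, `omega_normalized`, `p_value`,
#'   `significant`.
#' @export
weight_permutation_test <- function(session, n_perm = 10000, alpha = 0.05,
                                    control = fit_control(), seed = 1) {
  if (n_perm < 100) warn("n_perm < 100: permutation p-values are unstable")
  fit <- fit_estimator(session, "wgt", control = control)
  reg <- est_registry()[["wgt"]]
  idx <- seq_len(nrow(session))
  ctx0 <- estimator_context(session)
  local_ctl <- control
  local_ctl$maxit <- 150
  # observed and null statistics use the identical refit protocol (local
  # search from the neutral equal-weight start), so optimizer resolution
  # cancels out of the comparison
  refit_stat <- function(E) {
    ctx <- ctx0
    ctx$E <- E
    s0 <- c(rep(1, 4), mean(session$y) -
              mean(sqrt(as.vector(E^2 %*% rep(1, 4)) / 4)))
    abs(unname(fit_core(ctx, session$y, "wgt", reg, local_ctl, idx,
                        start = s0, local_only = TRUE)$theta))
  }
  obs <- refit_stat(ctx0$E)
  p <- with_seed(seed, vapply(seq_along(obs), function(n) {
    null_n <- vapply(seq_len(n_perm), function(i) {
      E <- ctx0$E
      E[, n] <- sample(E[, n])
      refit_stat(E)[n]
    }, numeric(1))
    (1 + sum(null_n >= obs[n])) / (n_perm + 1)
  }, numeric(1)))
  tibble(weight = seq_along(obs), omega = unname(fit$theta),
         omega_normalized = normalize_weights(unname(fit$theta)),
         p_value = p, significant = p < alpha)
}
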