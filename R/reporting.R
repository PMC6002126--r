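#' Binned response curve
#'
#' Mean response as a function of the sample's ML dispersion in equally
#' spaced bins, with percentile bootstrap confidence intervals. Empty bins
#' are omitted (flagged in the `empty_bins` attribute).
#'
#' @param session Session tibble with responses.
#' @param n_bins Number of equal-width bins over the observed `sigma_ml`
#'   range (default 10).
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param conf CI level (default 0.95).
#' @param seed Bootstrap seed.
#' @return Tibble with `bin`, `sigma_mid`, `mean_response`, `lower`,
#'   `upper`, `n`.
#' @export
binned_response_curve <- function(session, n_bins = 10, n_boot = 1000,
                                  conf = 0.95, seed = 1) {
  if (nrow(session) < n_bins) abort("fewer trials than bins")
  sml <- sigma_ml(session_d_matrix(session))
  edges <- seq(min(sml), max(sml), length.out = n_bins + 1)
  bin <- pmin(findInterval(sml, edges, rightmost.closed = TRUE), n_bins)
  alpha <- (1 - conf) / 2
  out <- with_seed(seed, purrr::map_dfr(seq_len(n_bins), function(b) {
    yy <- session$y[bin == b]
    if (length(yy) == 0) return(NULL)
    bm <- vapply(seq_len(n_boot), function(i)
      mean(sample(yy, replace = TRUE)), numeric(1))
    tibble(bin = b, sigma_mid = (edges[b] + edges[b + 1]) / 2,
           mean_response = mean(yy),
           lower = quantile(bm, alpha, names = FALSE),
           upper = quantile(bm, 1 - alpha, names = FALSE),
           n = length(yy))
  }))
  attr(out, "empty_bins") <- setdiff(seq_len(n_bins), out$bin)
  out
}

#' Capture-percentage compliance and stability
#'
#' Per participant: the median benchmark capture percentage, the median
#' absolute deviation from the 65% target, the same medians split by
#' experiment half, and (across participants) a one-sided Wilcoxon
#' signed-rank test of whether the capture deviation shrinks from the first
#' to the second half (i.e. whether feedback was used to re-calibrate).
#'
#' @param cohort Session tibble (one or many participants) with feedback
#'   column `c` (see [add_feedback()]).
#' @param target Target capture percentage.
#' @return List with `by_participant` (tibble) and `split_half_p` (Wilcoxon
#'   p-value; `NA` with fewer than 2 participants).
#' @export
capture_analysis <- function(cohort, target = TARGET_CAPTURE) {
  if (!"c" %in% names(cohort)) abort("cohort has no capture column `c`")
  by_p <- cohort %>%
    group_by(.data$participant_id) %>%
    summarise(
      median_c = median(.data$c),
      median_abs_dev = median(abs(.data$c - target)),
      first_half_dev = median(abs(.data$c[.data$trial <= max(.data$trial) / 2]
                                  - target)),
      second_half_dev = median(abs(.data$c[.data$trial > max(.data$trial) / 2]
                                   - target)),
      first_half_c = median(.data$c[.data$trial <= max(.data$trial) / 2]),
      second_half_c = median(.data$c[.data$trial > max(.data$trial) / 2]),
      .groups = "drop") %>%
    mutate(abs_half_diff = abs(.data$first_half_dev - .data$second_half_dev))
  p <- if (nrow(by_p) >= 2) {
    suppressWarnings(wilcox.test(by_p$first_half_dev, by_p$second_half_dev,
                                 paired = TRUE,
                                 alternative = "greater")$p.value)
  } else NA_real_
  list(by_participant = by_p, split_half_p = p)
}

#' Group weighting pattern
#'
#' Fits the weighting model to every participant, normalizes the weights to
#' sum to 4, and summarizes the group by per-rank medians with percentile
#' bootstrap confidence intervals.
#'
#' @param cohort Cohort session tibble.
#' @param control A [fit_control()].
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf CI level.
#' @param seed Bootstrap seed.
#' @return List of class `weighting_pattern`: `by_participant` (tibble of
#'   normalized weights) and `summary` (per-rank median and CI).
#' @export
weighting_pattern <- function(cohort, control = fit_control(),
                              n_boot = 10000, conf = 0.95, seed = 1) {
  ids <- unique(cohort$participant_id)
  W <- purrr::map_dfr(ids, function(id) {
    ses <- dplyr::filter(cohort, .data$participant_id == id)
    fit <- fit_estimator(ses, "wgt", control = control)
    tibble(participant_id = id, rank = 1:4,
           omega = unname(fit$omega_normalized))
  })
  out <- list(by_participant = W,
              summary = summarize_pattern(W, n_boot, conf, seed))
  class(out) <- "weighting_pattern"
  out
}

summarize_pattern <- function(W, n_boot, conf, seed) {
  alpha <- (1 - conf) / 2
  with_seed(seed, W %>%
    group_by(.data$rank) %>%
    dplyr::group_modify(function(df, key) {
      b <- vapply(seq_len(n_boot), function(i)
        median(sample(df$omega, replace = TRUE)), numeric(1))
      tibble(median_omega = median(df$omega),
             lower = quantile(b, alpha, names = FALSE),
             upper = quantile(b, 1 - alpha, names = FALSE))
    }) %>%
    ungroup())
}

#' Surrogate weighting pattern of a fitted model
#'
#' Asks what weighting pattern a candidate model would produce: the model is
#' fitted to each participant, its (noiseless) predictions replace the
#' responses at the same stimuli, and the weighting model is refitted to
#' these surrogate responses. A generator that weighs all points equally
#' (e.g. the normal model) yields a flat pattern; instance-based generators
#' elevate the third excentricity rank.
#'
#' @param cohort Cohort session tibble.
#' @param model_id The model whose surrogates are analysed.
#' @inheritParams weighting_pattern
#' @return A `weighting_pattern`.
#' @export
surrogate_weighting_refit <- function(cohort, model_id,
                                      control = fit_control(),
                                      n_boot = 10000, conf = 0.95, seed = 1) {
  ids <- unique(cohort$participant_id)
  W <- purrr::map_dfr(ids, function(id) {
    ses <- dplyr::filter(cohort, .data$participant_id == id)
    fit <- fit_estimator(ses, model_id, control = control)
    surr <- ses
    surr$y <- predict(fit, ses)
    wfit <- fit_estimator(surr, "wgt", control = control)
    tibble(participant_id = id, rank = 1:4,
           omega = unname(wfit$omega_normalized))
  })
  out <- list(by_participant = W,
              summary = summarize_pattern(W, n_boot, conf, seed))
  class(out) <- "weighting_pattern"
  out
}

#' Normalized-slope analysis
#'
#' Regresses the normalized response `y / sigma_ml` on the normalized
#' delta-KDE output `|d_(3)| / sigma_ml` per participant. Inference of a
#' Gaussian yields slope 0 by construction (responses depend on the sample
#' only through `sigma_ml`); pure instance-based delta-KDE behaviour yields
#' slope 1; intermediate kernel widths land in between, decreasing with the
#' width.
#'
#' @param cohort Cohort session tibble with responses.
#' @return Tibble with `participant_id`, `slope`, `intercept`.
#' @export
normalized_slope_analysis <- function(cohort) {
  cohort %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(function(df, key) {
      d <- session_d_matrix(df)
      sml <- sigma_ml(d)
      x <- delta_kde_response(d) / sml
      yn <- df$y / sml
      co <- coef(lm(yn ~ x))
      tibble(slope = unname(co[2]), intercept = unname(co[1]))
    }) %>%
    ungroup()
}

#' Count modes of a predictive density
#'
#' Number of strict local maxima of a mixture density on a fine grid spanning
#' the component support (for kernel mixtures: the most excentric centre plus
#' four kernel widths). Maxima closer than `1e-3` of the grid range merge
#' into one (plateau handling). Narrow kernels give one mode per distinct
#' point; very wide kernels merge all components into one.
#'
#' @param md A [mixture_density()].
#' @param n_grid Grid resolution (default 4096).
#' @return Integer mode count.
#' @export
count_modes <- function(md, n_grid = 4096) {
  stopifnot(inherits(md, "mixture_density"))
  span <- if (md$type == "gaussian") {
    max(abs(md$means)) + 4 * max(md$sds)
  } else {
    max(abs(c(md$lower, md$upper)))
  }
  x <- seq(-span, span, length.out = n_grid)
  f <- density_at(md, x)
  d <- diff(f)
  up <- d > 0
  # strict local maxima: rise followed by fall
  peaks <- which(up[-length(up)] & !up[-1]) + 1L
  if (length(peaks) <= 1) return(length(peaks))
  # merge peaks closer than 1e-3 of the range
  keep <- c(TRUE, diff(x[peaks]) > 1e-3 * (2 * span))
  sum(keep)
}

#' Participant exclusion by stimulus dependence
#'
#' Flags participants whose behaviour has little dependence on the stimulus,
#' operationalized as a cross-validated R-squared of the normal model below
#' `r2_threshold` (response regressed on `sigma_ml`, k-fold out-of-sample).
#'
#' @param cohort Cohort session tibble with responses.
#' @param r2_threshold Inclusion threshold on out-of-sample R-squared
#'   (default 0.2).
#' @param k Folds (default 5).
#' @param seed Fold seed.
#' @return Tibble with `participant_id`, `cv_r2`, `included`.
#' @export
exclusion_filter <- function(cohort, r2_threshold = 0.2, k = 5, seed = 1) {
  ids <- unique(cohort$participant_id)
  purrr::map_dfr(ids, function(id) {
    ses <- dplyr::filter(cohort, .data$participant_id == id)
    sml <- sigma_ml(session_d_matrix(ses))
    y <- ses$y
    folds <- with_seed(seed, sample(rep(seq_len(k), length.out = length(y))))
    pred <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      co <- coef(lm(y[tr] ~ sml[tr]))
      pred[!tr] <- co[1] + co[2] * sml[!tr]
    }
    r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    tibble(participant_id = id, cv_r2 = r2, included = r2 >= r2_threshold)
  })
}
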