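#' Maximum-likelihood dispersion of a zero-centred sample
#'
#' For offsets `d` of a distribution known to be centred at zero, the
#' maximum-likelihood estimate of the standard deviation is
#' `sqrt(mean(d^2))` (the root-mean-square deviation). This is the sufficient
#' statistic for scale inference from a centred Gaussian sample.
#'
#' @param d Numeric vector of signed offsets (one trial), or a numeric matrix
#'   with one trial per row.
#' @return A nonnegative scalar (or one value per row for matrix input).
#' @examples
#' sigma_ml(c(12, 16, 0, 0)) # 10
#' @export
sigma_ml <- function(d) {
  if (is.matrix(d)) {
    if (ncol(d) < 1L) abort("empty sample")
    return(sqrt(rowMeans(d^2)))
  }
  if (length(d) == 0L || !is.numeric(d)) abort("empty sample")
  sqrt(mean(d^2))
}

#' Stimulus generator configuration
#'
#' @param nu_range Interval (pixels) from which the target dispersion `nu` is
#'   drawn uniformly on each trial. Default `c(10, 140)`.
#' @param n_trials Number of trials per session (default 320).
#' @param n_points Points per trial (default 4).
#' @param renormalize If `TRUE` (default) raw standard-normal draws are scaled
#'   so the sample's maximum-likelihood dispersion equals `nu` exactly; if
#'   `FALSE` the sample is simply `nu * r` (long-tailed comparison scheme).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(nu_range = c(10, 140), n_trials = 320,
                             n_points = 4, renormalize = TRUE) {
  stopifnot(length(nu_range) == 2, nu_range[1] > 0, nu_range[2] > nu_range[1],
            n_trials >= 1, n_points >= 1)
  structure(list(nu_range = nu_range, n_trials = as.integer(n_trials),
                 n_points = as.integer(n_points),
                 renormalize = isTRUE(renormalize)),
            class = "generator_config")
}

#' Generate one trial sample
#'
#' Draws `n_points` standard-normal offsets `r` and rescales them by
#' `nu / sigma_ml(r)` so that the scaled sample's ML dispersion equals `nu`
#' exactly. A measure-zero all-zero raw draw is redrawn.
#'
#' @param nu Target dispersion (pixels), > 0.
#' @param n_points Points per trial.
#' @param renormalize If `FALSE`, return `nu * r` without rescaling.
#' @return Numeric vector of signed offsets (pixels).
#' @export
generate_trial <- function(nu, n_points = 4, renormalize = TRUE) {
  stopifnot(is.numeric(nu), length(nu) == 1, nu > 0)
  repeat {
    r <- rnorm(n_points)
    s <- sigma_ml(r)
    if (s > 0) break
  }
  if (renormalize) nu / s * r else nu * r
}

#' Generate a full session of trials
#'
#' Each trial draws a fresh target dispersion `nu ~ Uniform(nu_range)` and a
#' renormalized standard-normal sample whose ML dispersion equals `nu`. With a
#' fixed `seed` the session is reproducible, and each trial is reproducible in
#' isolation: trial `t` uses a substream seeded deterministically from the
#' master seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed (optional).
#' @param participant_id Identifier stored in the session tibble.
#' @return A session tibble with columns `participant_id`, `trial`,
#'   `d1`..`d<n_points>`, `nu`.
#' @export
generate_session <- function(config = generator_config(), seed = NULL,
                             participant_id = "sim") {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  # per-trial substream seeds derived from the master stream
  sub <- sample.int(.Machine$integer.max %/% 2L, config$n_trials)
  rows <- lapply(seq_len(config$n_trials), function(t) {
    set.seed(sub[t])
    nu <- runif(1, config$nu_range[1], config$nu_range[2])
    d <- generate_trial(nu, config$n_points, config$renormalize)
    c(d, nu)
  })
  m <- do.call(rbind, rows)
  out <- as_tibble(as.data.frame(m),
                   .name_repair = ~ c(paste0("d", seq_len(config$n_points)), "nu"))
  out <- dplyr::bind_cols(tibble(participant_id = participant_id,
                                 trial = seq_len(config$n_trials)), out)
  attr(out, "generator_config") <- config
  out
}

#' @rdname generate_session
#' @details `generate_unnormalized_session()` is a convenience wrapper using
#'   the non-renormalized scheme `d = nu * r`, for reproducing the long-tailed
#'   comparison histogram of ML dispersions.
#' @export
generate_unnormalized_session <- function(config = generator_config(),
                                          seed = NULL,
                                          participant_id = "sim") {
  config$renormalize <- FALSE
  generate_session(config, seed = seed, participant_id = participant_id)
}

# ---- internal session helpers -----------------------------------------------

# columns d1..dK of a session as an n x K matrix
session_d_matrix <- function(session) {
  dcols <- grep("^d[0-9]+$", names(session), value = TRUE)
  if (length(dcols) == 0L) abort("session has no d1..dN columns")
  as.matrix(session[dcols])
}

# excentricity-sorted |d| (ascending within each row)
excentricity_matrix <- function(d) {
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  t(apply(abs(d), 1, sort))
}

# signed values sorted ascending within each row (for range / tiling)
sorted_signed_matrix <- function(d) {
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  t(apply(d, 1, sort))
}
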