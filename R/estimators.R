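#' Heuristic and inference dispersion estimators
#'
#' Every candidate model shares the two-step structure `d -> S(d) -> yhat`:
#' a dispersion estimate `S` computed from the four offsets, followed by the
#' affine response mapping [apply_response_mapping()]. The estimators:
#' \describe{
#'   \item{`s_max()`}{distance of the most excentric point, `max(|d|)`.}
#'   \item{`s_range()`}{spread between leftmost and rightmost point,
#'     `max(d) - min(d)`.}
#'   \item{`s_weighting()`}{generalized RMS `sqrt(mean(omega_n * d_n^2))` with
#'     one weight per excentricity rank (ascending `|d|`); unit weights
#'     reproduce [sigma_ml()].}
#'   \item{`s_gnorm()`}{scale MLE of a centred generalized normal with shape
#'     `p`: `(p/N * sum(|d_n|^p))^(1/p)`; `p = 2` gives `sqrt(2) * sigma_ml`,
#'     `p -> Inf` approaches `s_max`.}
#' }
#'
#' @param d Numeric vector (one trial) or matrix (trials in rows) of signed
#'   offsets.
#' @return One estimate per trial.
#' @name estimators
NULL

#' @rdname estimators
#' @export
s_max <- function(d) {
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  apply(abs(d), 1, max)
}

#' @rdname estimators
#' @export
s_range <- function(d) {
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  apply(d, 1, max) - apply(d, 1, min)
}

#' @rdname estimators
#' @param omega Nonnegative weights, one per excentricity rank (ascending).
#' @export
s_weighting <- function(d, omega) {
  if (any(omega < 0)) abort("weights must be nonnegative")
  e <- excentricity_matrix(d)
  if (length(omega) != ncol(e)) abort("one weight per point required")
  sqrt(as.vector(e^2 %*% omega) / ncol(e))
}

#' @rdname estimators
#' @param p Shape exponent of the generalized normal, > 0.
#' @export
s_gnorm <- function(d, p) {
  if (p <= 0) abort("shape exponent p must be positive")
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  (p * rowMeans(abs(d)^p))^(1 / p)
}

#' Normalize weighting-model weights
#'
#' Rescales fitted weights to satisfy `sum(omega) == N` so they read as
#' relative contributions against the equal-weight (Gaussian-inference) case
#' `omega_n = 1`; the factored-out scale belongs to the response mapping.
#'
#' @param omega Nonnegative weights.
#' @return Weights summing to `length(omega)`.
#' @export
normalize_weights <- function(omega) {
  stopifnot(all(omega >= 0), sum(omega) > 0)
  omega * length(omega) / sum(omega)
}

#' Affine response mapping
#'
#' Maps a dispersion estimate onto the predicted half-frame width:
#' `yhat = beta0 + beta1 * S (+ beta2 * S^2)`. The shared first-order mapping
#' absorbs subjective prior knowledge and probability distortion; the
#' quadratic term is an optional test variant, off by default.
#'
#' @param S Dispersion estimate(s).
#' @param beta0,beta1,beta2 Mapping coefficients.
#' @return Predicted response(s).
#' @export
apply_response_mapping <- function(S, beta0, beta1, beta2 = 0) {
  beta0 + beta1 * S + beta2 * S^2
}

# ---- kernel density estimation ---------------------------------------------

#' Kernel width rule for the KDE model
#'
#' `eta = a * (e3 + e4) / 2` where `e3`, `e4` are the two largest
#' excentricities (absolute offsets); absolute values keep the width positive.
#'
#' @inheritParams estimators
#' @param a Width factor, > 0.
#' @export
kde_width <- function(d, a) {
  if (a <= 0) abort("kernel width factor a must be positive")
  e <- excentricity_matrix(d)
  k <- ncol(e)
  a * (e[, k - 1] + e[, k]) / 2
}

#' KDE predictive density for one trial
#'
#' Centres a Gaussian kernel of width `eta(d) = a * (e3 + e4)/2` on each
#' observation: `p(x | d) = mean_n N(x | d_n, eta)`.
#'
#' @inheritParams kde_width
#' @return A [mixture_density()] with one component per observation.
#' @export
kde_predictive <- function(d, a) {
  stopifnot(!is.matrix(d))
  eta <- kde_width(d, a)
  if (eta == 0) abort("kernel width is zero (top excentricities are zero)")
  mixture_density("gaussian", means = d, sds = rep(eta, length(d)))
}

#' KDE model response
#'
#' Solves the capture equation against the KDE predictive density: the
#' half-frame width `y` whose symmetric interval holds `target` of the kernel
#' mixture's mass. Vectorized over trials by joint bisection. Degenerate
#' trials with zero kernel width fall back to the delta-KDE response.
#'
#' @inheritParams kde_width
#' @param target Target capture percentage.
#' @param tol Tolerance on the capture probability.
#' @export
kde_response <- function(d, a, target = TARGET_CAPTURE, tol = 1e-10) {
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  eta <- kde_width(d, a)
  out <- numeric(nrow(d))
  zero <- eta == 0
  if (any(zero)) out[zero] <- delta_kde_response(d[zero, , drop = FALSE])
  if (any(!zero)) {
    dd <- d[!zero, , drop = FALSE]
    ee <- eta[!zero]
    cfun <- function(z) {
      acc <- 0
      for (j in seq_len(ncol(dd)))
        acc <- acc + pnorm((z - dd[, j]) / ee) - pnorm((-z - dd[, j]) / ee)
      acc / ncol(dd)
    }
    upper <- apply(abs(dd), 1, max) + 6 * ee
    out[!zero] <- bisect_capture_vec(cfun, target, upper = upper, tol = tol)
  }
  out
}

#' Vanishing-kernel-width (delta-KDE) response
#'
#' In the limit `a -> 0` the KDE kernels become delta distributions and the
#' 65% response converges to the third most excentric point (ascending
#' excentricity rank 3 of 4): the smallest frame capturing 3 of the 4 points.
#'
#' @inheritParams estimators
#' @export
delta_kde_response <- function(d) {
  e <- excentricity_matrix(d)
  if (ncol(e) != 4L) abort("delta-KDE response is defined for 4-point samples")
  e[, 3]
}

# ---- tiling model -----------------------------------------------------------

#' Tiling predictive density for one trial
#'
#' Tiles the space between the position-sorted points into adjacent,
#' non-overlapping uniform basis distributions such that the sorted points sit
#' at the cumulative quantiles `(i - 0.5)/N`. Each interior interval carries
#' mass `1/N`; the two tails are uniforms of mass `0.5/N` whose support equals
#' the distance to the single adjacent point. Coincident points would create
#' zero-width tiles; their shared mass is spread over a 1e-6 px interval (with
#' a warning) to keep the CDF well defined.
#'
#' @param d Numeric vector of signed offsets (one trial).
#' @return A [mixture_density()] of type `"uniform"`.
#' @export
tiling_density <- function(d) {
  stopifnot(!is.matrix(d))
  s <- sort(d)
  n <- length(s)
  lower <- c(s[1] - (s[2] - s[1]), s[-n])
  upper <- c(s[1], s[-1])
  upper <- c(upper, s[n] + (s[n] - s[n - 1]))
  lower <- c(lower, s[n])
  w <- c(0.5 / n, rep(1 / n, n - 1), 0.5 / n)
  zw <- upper - lower <= 0
  if (any(zw)) {
    warn("coincident points in tiling model; spreading mass over 1e-6 px")
    upper[zw] <- lower[zw] + 1e-6
  }
  mixture_density("uniform", lower = lower, upper = upper, weights = w)
}

#' Tiling model response
#'
#' Inverts the tiling density's capture probability for the frame half-width
#' capturing `target` of its mass. The capture probability is piecewise
#' linear in the half-width with breakpoints at the absolute tile bounds, so
#' the inversion is exact (linear interpolation on the crossing segment).
#'
#' @inheritParams kde_response
#' @export
tiling_response <- function(d, target = TARGET_CAPTURE) {
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  vapply(seq_len(nrow(d)), function(i) {
    md <- tiling_density(d[i, ])
    z <- sort(unique(c(0, abs(md$lower), abs(md$upper))))
    cz <- capture_probability(md, z)
    if (target <= cz[1]) return(0)
    k <- findInterval(target, cz, rightmost.closed = TRUE)
    if (k >= length(z)) return(z[length(z)])
    if (cz[k + 1] == cz[k]) return(z[k + 1])
    z[k] + (target - cz[k]) / (cz[k + 1] - cz[k]) * (z[k + 1] - z[k])
  }, numeric(1))
}

# ---- baseline and history regressors ---------------------------------------

#' Baseline and history estimators
#'
#' `s_baseline()` predicts the mean training response on every trial (a
#' stimulus-independent lower bound on predictability). `s_prev_response()`
#' uses the previously stated response; `s_prev_feedback()` the most recently
#' presented block capture-percentage feedback (shown after every 5 trials).
#' Trials with no history yet are imputed with `fill` (the training-set mean
#' response during fitting).
#'
#' @param y_train Training responses.
#' @export
s_baseline <- function(y_train) mean(y_train)

#' @rdname s_baseline
#' @param session Session tibble (needs `y`; `block_c` for the feedback
#'   variant).
#' @param fill Imputation value for trials without history (defaults to the
#'   session mean response).
#' @export
s_prev_response <- function(session, fill = NULL) {
  y <- session$y
  if (is.null(fill)) fill <- mean(y)
  c(fill, y[-length(y)])
}

#' @rdname s_baseline
#' @param block_size Trials per feedback block.
#' @export
s_prev_feedback <- function(session, block_size = 5, fill = NULL) {
  if (!all(c("block", "block_c") %in% names(session)))
    abort("session has no block feedback columns; run add_feedback() first")
  t <- seq_len(nrow(session))
  last_block <- (t - 1L) %/% block_size   # completed blocks before trial t
  bc <- session$block_c[!duplicated(session$block)]
  out <- ifelse(last_block >= 1L, bc[pmax(last_block, 1L)], NA_real_)
  if (is.null(fill)) fill <- mean(out, na.rm = TRUE)
  out[is.na(out)] <- fill
  out
}

# ---- registry ---------------------------------------------------------------

#' Catalogue of candidate models
#'
#' One row per model in the zoo, with its identifier and free parameters. The
#' `wgt` model fixes `beta1 = 1` (scale is absorbed into the weights); history
#' and baseline models depend on the training responses rather than the
#' stimulus.
#'
#' @return A tibble with columns `model_id`, `params`, `description`.
#' @export
estimator_catalog <- function() {
  reg <- est_registry()
  tibble(model_id = names(reg),
         params = vapply(reg, function(r)
           paste(c("beta0", if (!r$beta1_fixed) "beta1", r$theta_names),
                 collapse = ","), character(1)),
         description = vapply(reg, function(r) r$description, character(1)))
}

# internal registry: S_fun(ctx, theta) -> per-trial dispersion estimate.
# ctx: list(D, E, Dsort, sml, session, train_mean_y)
est_registry <- function() {
  list(
    max = list(theta_names = character(), theta_lower = numeric(),
               theta_upper = numeric(), beta1_fixed = FALSE,
               description = "most excentric point",
               S_fun = function(ctx, theta) s_max(ctx$D)),
    rng = list(theta_names = character(), theta_lower = numeric(),
               theta_upper = numeric(), beta1_fixed = FALSE,
               description = "range between leftmost and rightmost point",
               S_fun = function(ctx, theta) s_range(ctx$D)),
    wgt = list(theta_names = paste0("w", 1:4), theta_lower = rep(0, 4),
               theta_upper = rep(16, 4), beta1_fixed = TRUE,
               description = "excentricity-weighted RMS (beta1 = 1)",
               S_fun = function(ctx, theta)
                 sqrt(as.vector(ctx$E^2 %*% theta) / ncol(ctx$E))),
    nm = list(theta_names = character(), theta_lower = numeric(),
              theta_upper = numeric(), beta1_fixed = FALSE,
              description = "zero-centred Gaussian ML dispersion",
              S_fun = function(ctx, theta) ctx$sml),
    gnm = list(theta_names = "p", theta_lower = 0.1, theta_upper = 50,
               beta1_fixed = FALSE,
               description = "generalized normal scale MLE with shape p",
               S_fun = function(ctx, theta) s_gnorm(ctx$D, theta[1])),
    kde = list(theta_names = "a", theta_lower = 1e-3, theta_upper = 5,
               beta1_fixed = FALSE,
               description = "Gaussian kernel density 65% response",
               S_fun = function(ctx, theta) kde_response(ctx$D, theta[1])),
    delta_kde = list(theta_names = character(), theta_lower = numeric(),
                     theta_upper = numeric(), beta1_fixed = FALSE,
                     description = "third most excentric point (KDE limit)",
                     S_fun = function(ctx, theta) delta_kde_response(ctx$D)),
    tlg = list(theta_names = character(), theta_lower = numeric(),
               theta_upper = numeric(), beta1_fixed = FALSE,
               description = "piecewise-uniform tiling 65% response",
               S_fun = function(ctx, theta) tiling_response(ctx$D)),
    baseline = list(theta_names = character(), theta_lower = numeric(),
                    theta_upper = numeric(), beta1_fixed = FALSE,
                    description = "training mean response on every trial",
                    S_fun = function(ctx, theta)
                      rep(ctx$train_mean_y, nrow(ctx$D))),
    prev_resp = list(theta_names = character(), theta_lower = numeric(),
                     theta_upper = numeric(), beta1_fixed = FALSE,
                     description = "previously stated response",
                     S_fun = function(ctx, theta)
                       s_prev_response(ctx$session, fill = ctx$train_mean_y)),
    prev_fb = list(theta_names = character(), theta_lower = numeric(),
                   theta_upper = numeric(), beta1_fixed = FALSE,
                   description = "most recent block capture feedback",
                   S_fun = function(ctx, theta)
                     s_prev_feedback(ctx$session, fill = ctx$train_mean_y))
  )
}

# precompute the per-session quantities the estimators consume
estimator_context <- function(session, train_mean_y = NULL) {
  D <- session_d_matrix(session)
  list(D = D,
       E = excentricity_matrix(D),
       Dsort = sorted_signed_matrix(D),
       sml = sigma_ml(D),
       session = session,
       train_mean_y = if (is.null(train_mean_y) && "y" %in% names(session))
         mean(session$y) else train_mean_y)
}
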