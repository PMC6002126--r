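#' Posterior over the dispersion of a centred Gaussian
#'
#' Given one trial's offsets `d`, computes the posterior over the standard
#' deviation `sigma` of the zero-mean Gaussian assumed to have generated them:
#' `p(sigma | d) \propto prod_n N(d_n | 0, sigma) * p(sigma)` with a uniform
#' prior on `prior_bounds`. The posterior is represented numerically on a
#' log-spaced grid. The prior's stated lower bound of 0 is numerically
#' unusable (the likelihood diverges as `sigma -> 0` for degenerate all-zero
#' samples), so the grid starts at a small positive guard `sigma_min`; an
#' all-zero sample is flagged and its mass concentrates at the guard.
#'
#' @param d Numeric vector of signed offsets (one trial).
#' @param prior_bounds Support of the uniform prior on sigma (pixels),
#'   default `c(0, 140)`.
#' @param n_grid Number of grid nodes (default 2000, log-spaced).
#' @param sigma_min Lower grid guard (default 1e-3 px).
#' @return An object of class `sigma_posterior` with fields `sigma_grid`,
#'   `weights` (masses summing to 1), `mode`, and `degenerate`.
#' @export
posterior_sigma <- function(d, prior_bounds = c(0, 140), n_grid = 2000,
                            sigma_min = 1e-3) {
  stopifnot(is.numeric(d), length(d) >= 1)
  grid <- sigma_grid(prior_bounds, n_grid, sigma_min)
  degenerate <- all(d == 0)
  n <- length(d)
  s2 <- mean(d^2)
  # log N(d | 0, sigma) summed over points, up to a constant
  ll <- -n * log(grid$sigma) - n * s2 / (2 * grid$sigma^2)
  ll <- ll - max(ll)
  w <- exp(ll) * grid$dw
  w <- w / sum(w)
  structure(list(sigma_grid = grid$sigma, weights = w,
                 mode = grid$sigma[which.max(ll)],
                 prior_bounds = prior_bounds, n = n,
                 degenerate = degenerate),
            class = "sigma_posterior")
}

# shared log-spaced grid with trapezoid quadrature weights
sigma_grid <- function(prior_bounds = c(0, 140), n_grid = 2000,
                       sigma_min = 1e-3) {
  upper <- prior_bounds[2]
  stopifnot(upper > sigma_min)
  s <- exp(seq(log(sigma_min), log(upper), length.out = n_grid))
  dw <- c(diff(s) / 2, 0) + c(0, diff(s) / 2)
  list(sigma = s, dw = dw)
}

#' Predictive density of the ideal observer
#'
#' Marginalizes the Gaussian observation model over the posterior on sigma:
#' `p(x | d) = int N(x | 0, sigma) p(sigma | d) dsigma`, evaluated as a
#' zero-mean Gaussian scale mixture on the posterior grid. The result is
#' symmetric about zero, unimodal at zero, and heavier-tailed than any single
#' component.
#'
#' @param post A [posterior_sigma()] object.
#' @return A [mixture_density()] of type `"gaussian"`.
#' @export
predictive_density <- function(post) {
  stopifnot(inherits(post, "sigma_posterior"))
  keep <- post$weights > 0
  mixture_density("gaussian",
                  means = rep(0, sum(keep)),
                  sds = post$sigma_grid[keep],
                  weights = post$weights[keep])
}

#' Benchmark responses for a whole session
#'
#' For each trial, forms the ideal-observer posterior over sigma, the
#' predictive density over the next event, and returns the half-frame width
#' whose capture probability equals `target`. All trials are solved jointly by
#' vectorized bisection on the shared posterior grid.
#'
#' @param session A session tibble (columns `d1..dN`).
#' @param target Target capture percentage (default 0.65).
#' @param prior_bounds,n_grid,sigma_min Posterior grid controls, see
#'   [posterior_sigma()].
#' @param tol Tolerance on the capture probability at the returned response.
#' @return The session with a `y_benchmark` column appended.
#' @export
benchmark_response <- function(session, target = TARGET_CAPTURE,
                               prior_bounds = c(0, 140), n_grid = 2000,
                               sigma_min = 1e-3, tol = 1e-10) {
  W <- benchmark_weights(session, prior_bounds, n_grid, sigma_min)
  g <- attr(W, "sigma")
  cfun <- function(z) {
    P <- pnorm(outer(z, 1 / g))        # n x G
    2 * rowSums(W * P) - 1
  }
  upper <- pmax(10 * sigma_ml(session_d_matrix(session)), prior_bounds[2])
  y <- bisect_capture_vec(cfun, target, upper = upper, tol = tol / 10)
  dplyr::mutate(session, y_benchmark = y)
}

#' Benchmark capture percentage of arbitrary responses
#'
#' Evaluates, for each trial, the probability mass of the ideal-observer
#' predictive density inside the symmetric frame set by `y` — the quantity the
#' task's feedback is based on.
#'
#' @inheritParams benchmark_response
#' @param y Responses (half-frame widths); defaults to the session's `y`
#'   column.
#' @return Numeric vector of capture percentages in `[0, 1]`.
#' @export
benchmark_capture <- function(session, y = NULL, prior_bounds = c(0, 140),
                              n_grid = 2000, sigma_min = 1e-3) {
  if (is.null(y)) {
    if (!"y" %in% names(session)) abort("session has no `y` column")
    y <- session$y
  }
  W <- benchmark_weights(session, prior_bounds, n_grid, sigma_min)
  g <- attr(W, "sigma")
  2 * rowSums(W * pnorm(outer(y, 1 / g))) - 1
}

# posterior mass matrix (trials x grid), shared grid in attr "sigma"
benchmark_weights <- function(session, prior_bounds = c(0, 140),
                              n_grid = 2000, sigma_min = 1e-3) {
  d <- session_d_matrix(session)
  grid <- sigma_grid(prior_bounds, n_grid, sigma_min)
  n <- ncol(d)
  s2 <- rowMeans(d^2)
  L <- outer(-n * s2 / 2, 1 / grid$sigma^2) -
    matrix(n * log(grid$sigma), nrow(d), n_grid, byrow = TRUE)
  L <- L - apply(L, 1, max)
  W <- exp(L) * matrix(grid$dw, nrow(d), n_grid, byrow = TRUE)
  W <- W / rowSums(W)
  attr(W, "sigma") <- grid$sigma
  W
}

#' Trial and block feedback
#'
#' The task scores each response by the benchmark capture percentage `c` and
#' the deviation score `delta = (c - 0.65)^2 * 1000`; participants see both
#' averaged over consecutive 5-trial blocks.
#'
#' `trial_feedback()` scores a single response against a predictive density;
#' `add_feedback()` appends per-trial and per-block feedback columns (`c`,
#' `delta`, `block`, `block_c`, `block_delta`) to a session with responses.
#'
#' @param pd A [mixture_density()].
#' @param y Response (half-frame width), nonnegative.
#' @param target Target capture percentage.
#' @return `trial_feedback()`: a list with `c` and `delta`.
#' @export
trial_feedback <- function(pd, y, target = TARGET_CAPTURE) {
  stopifnot(y >= 0)
  cc <- capture_probability(pd, y)
  list(c = cc, delta = (cc - target)^2 * 1000)
}

#' @rdname trial_feedback
#' @param session Session tibble with a `y` column.
#' @param block_size Trials per feedback block (default 5).
#' @param ... Grid controls passed to [benchmark_capture()].
#' @export
add_feedback <- function(session, target = TARGET_CAPTURE, block_size = 5,
                         ...) {
  cc <- benchmark_capture(session, ...)
  session %>%
    mutate(c = cc,
           delta = (cc - target)^2 * 1000,
           block = (row_number() - 1L) %/% block_size + 1L) %>%
    group_by(.data$participant_id, .data$block) %>%
    mutate(block_c = mean(.data$c), block_delta = mean(.data$delta)) %>%
    ungroup()
}

#' @rdname trial_feedback
#' @param feedback A data frame with `c` and `delta` columns (one block).
#' @export
block_feedback <- function(feedback) {
  list(c = mean(feedback$c), delta = mean(feedback$delta))
}

#' @export
print.sigma_posterior <- function(x, ...) {
  cat(sprintf("<sigma_posterior: %d nodes on [%g, %g], mode %.3f%s>\n",
              length(x$sigma_grid), min(x$sigma_grid), max(x$sigma_grid),
              x$mode, if (x$degenerate) ", degenerate sample" else ""))
  invisible(x)
}
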