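#' Mixture predictive densities
#'
#' Predictive beliefs about the position of the next event are represented as
#' finite mixtures: zero-mean Gaussian scale mixtures (ideal observer),
#' equal-weight Gaussian location mixtures (kernel density estimation), or
#' piecewise-uniform tilings. The container supports pointwise density and CDF
#' evaluation, the capture probability of a symmetric frame, and inversion of
#' the capture probability for a target percentage.
#'
#' @param type `"gaussian"` or `"uniform"`.
#' @param means,sds Component centres and SDs (Gaussian type).
#' @param lower,upper Component supports (uniform type).
#' @param weights Component weights; normalized to sum to one.
#' @return An object of class `mixture_density`.
#' @export
mixture_density <- function(type = c("gaussian", "uniform"),
                            means = NULL, sds = NULL,
                            lower = NULL, upper = NULL, weights = NULL) {
  type <- match.arg(type)
  if (type == "gaussian") {
    stopifnot(length(means) == length(sds), all(sds > 0))
    k <- length(means)
  } else {
    stopifnot(length(lower) == length(upper), all(upper > lower))
    k <- length(lower)
  }
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(weights) == k, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  structure(list(type = type, means = means, sds = sds,
                 lower = lower, upper = upper, weights = weights),
            class = "mixture_density")
}

#' @rdname mixture_density
#' @param md A `mixture_density`.
#' @param x Positions at which to evaluate.
#' @export
density_at <- function(md, x) {
  stopifnot(inherits(md, "mixture_density"))
  if (md$type == "gaussian") {
    vapply(x, function(xi) sum(md$weights * dnorm(xi, md$means, md$sds)),
           numeric(1))
  } else {
    vapply(x, function(xi) {
      sum(md$weights * as.numeric(xi >= md$lower & xi < md$upper) /
            (md$upper - md$lower))
    }, numeric(1))
  }
}

#' @rdname mixture_density
#' @export
cdf_at <- function(md, x) {
  stopifnot(inherits(md, "mixture_density"))
  if (md$type == "gaussian") {
    vapply(x, function(xi) sum(md$weights * pnorm(xi, md$means, md$sds)),
           numeric(1))
  } else {
    vapply(x, function(xi) {
      sum(md$weights * pmin(1, pmax(0, (xi - md$lower) / (md$upper - md$lower))))
    }, numeric(1))
  }
}

#' Capture probability of a symmetric frame
#'
#' Probability mass of a predictive density inside the symmetric interval
#' `[-z, z]` — the fraction of future events a frame of half-width `z` would
#' capture.
#'
#' @param md A [mixture_density()].
#' @param z Nonnegative half-frame width(s), pixels.
#' @return Values in `[0, 1]`.
#' @export
capture_probability <- function(md, z) {
  if (any(z < 0)) abort("frame half-width z must be nonnegative")
  cdf_at(md, z) - cdf_at(md, -z)
}

#' Frame size matching a target capture percentage
#'
#' Inverts the capture probability: returns the half-frame width `y` with
#' `capture_probability(md, y) == target`. The capture probability is
#' continuous and nondecreasing in `y`, so bisection converges; the root is
#' refined until the capture probability is within `tol` of the target.
#'
#' @param md A [mixture_density()].
#' @param target Target capture percentage in (0, 1); default 0.65.
#' @param tol Tolerance on the capture probability at the returned root.
#' @return Nonnegative half-frame width (pixels).
#' @export
solve_response <- function(md, target = TARGET_CAPTURE, tol = 1e-8) {
  stopifnot(target > 0, target < 1)
  upper <- if (md$type == "gaussian") {
    max(abs(md$means) + 10 * md$sds)
  } else {
    max(abs(c(md$lower, md$upper)))
  }
  bisect_capture(function(z) capture_probability(md, z), target,
                 lower = 0, upper = upper, tol = tol)
}

# scalar bisection on a monotone capture function; tolerance on the capture
# value itself, with interval refinement down to machine precision
bisect_capture <- function(cfun, target, lower, upper, tol = 1e-8,
                           max_iter = 200L) {
  while (cfun(upper) < target) upper <- upper * 2
  lo <- lower; hi <- upper
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cm <- cfun(mid)
    if (abs(cm - target) < tol || (hi - lo) < .Machine$double.eps * max(1, hi))
      return(mid)
    if (cm < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# vectorized bisection: cfun(z) takes and returns a vector (one per trial)
bisect_capture_vec <- function(cfun, target, upper, tol = 1e-10,
                               max_iter = 80L) {
  n <- length(upper)
  lo <- rep(0, n); hi <- upper
  # expand where needed
  for (j in 1:30) {
    ch <- cfun(hi)
    bad <- ch < target
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cm <- cfun(mid)
    below <- cm < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol * pmax(1, max(hi))) break
  }
  (lo + hi) / 2
}

#' @export
print.mixture_density <- function(x, ...) {
  k <- length(x$weights)
  cat(sprintf("<mixture_density: %d %s component%s>\n", k, x$type,
              if (k == 1) "" else "s"))
  invisible(x)
}
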