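#' Lapse floor of the response likelihood
#'
#' The constant density added to every trial's Gaussian response likelihood so
#' that outlying responses keep nonzero probability. Fixed (not fitted) at the
#' standard normal density four standard deviations from the mean, 1.34e-4.
#'
#' @export
lapse_epsilon <- function() 1.34e-4

#' Heteroscedastic quantile-binned noise model
#'
#' Response variability grows with the predicted response, so instead of a
#' parametric noise law the predicted responses `yhat` are divided into `Q`
#' equally filled quantile bins and a separate SD `theta_q` is estimated in
#' each: `theta_q = sqrt(mean((y - yhat)^2))` over the bin's trials. Before
#' estimating `theta_q`, residuals lying more than two interquartile ranges
#' below the lower or above the upper quartile (of the bin's residuals) are
#' trimmed; the trimming applies to `theta` estimation only, never to the
#' likelihood. Bins left empty (or with zero spread) are floored at 1e-3 px
#' with a warning.
#'
#' @param predicted Model predictions `yhat`, one per trial.
#' @param observed Observed responses `y`.
#' @param Q Number of quantile bins (default 5).
#' @param epsilon Lapse floor (default [lapse_epsilon()]).
#' @return An object of class `noise_model` with fields `Q`, `edges`,
#'   `theta`, `epsilon`.
#' @export
bin_thetas <- function(predicted, observed, Q = 5, epsilon = lapse_epsilon()) {
  stopifnot(length(predicted) == length(observed), epsilon >= 0)
  if (length(predicted) < 2 * Q)
    abort("need at least 2 trials per quantile bin")
  edges <- unique(quantile(predicted, probs = seq(0, 1, length.out = Q + 1),
                           names = FALSE, type = 7))
  # interior edges only; outermost bins are open-ended for new data
  interior <- edges[-c(1, length(edges))]
  bins <- assign_bins_edges(predicted, interior)
  nbin <- length(interior) + 1L
  theta <- vapply(seq_len(nbin), function(q) {
    r <- (observed - predicted)[bins == q]
    if (length(r) == 0) return(NA_real_)
    qs <- quantile(r, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    keep <- r >= qs[1] - 2 * iqr & r <= qs[2] + 2 * iqr
    if (!any(keep)) return(NA_real_)
    sqrt(mean(r[keep]^2))
  }, numeric(1))
  bad <- is.na(theta) | theta < 1e-3
  if (any(bad)) {
    warn("noise bin with no usable residuals; flooring theta at 1e-3 px")
    theta[bad] <- pmax(theta[bad], 1e-3, na.rm = TRUE)
    theta[is.na(theta)] <- 1e-3
  }
  structure(list(Q = nbin, edges = interior, theta = theta, epsilon = epsilon),
            class = "noise_model")
}

# ties at edges go to the lower bin (intervals open on the left)
assign_bins_edges <- function(x, interior) {
  findInterval(x, interior, left.open = TRUE) + 1L
}

#' @rdname bin_thetas
#' @param noise A `noise_model`.
#' @export
assign_bins <- function(noise, predicted) {
  assign_bins_edges(predicted, noise$edges)
}

#' Log-likelihood of observed responses
#'
#' The per-trial response density is a two-part mixture: a Gaussian centred on
#' the model prediction with the bin-specific SD, plus the constant lapse
#' floor `epsilon` so that no finite response has vanishing likelihood:
#' `(1 - epsilon) * N(y | yhat, theta_q) + epsilon`. The floor makes the
#' density improper by a negligible amount; it is applied literally, and no
#' trial is ever excluded from the likelihood.
#'
#' @param observed Observed responses.
#' @param predicted Model predictions (same length).
#' @param noise A [bin_thetas()] noise model (bin edges from training data).
#' @param per_trial If `TRUE` return the per-trial log densities instead of
#'   their sum.
#' @return Scalar log-likelihood (or per-trial vector).
#' @export
response_loglik <- function(observed, predicted, noise, per_trial = FALSE) {
  stopifnot(inherits(noise, "noise_model"),
            length(observed) == length(predicted))
  th <- noise$theta[assign_bins(noise, predicted)]
  ll <- log((1 - noise$epsilon) * dnorm(observed, predicted, th) +
              noise$epsilon)
  if (per_trial) ll else sum(ll)
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model: Q = %d, theta = [%s] px, epsilon = %.3g>\n",
              x$Q, paste(sprintf("%.2f", x$theta), collapse = ", "),
              x$epsilon))
  invisible(x)
}
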