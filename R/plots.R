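#' Plot a binned response curve
#'
#' Mean response (with bootstrap CI ribbon) against the sample's ML
#' dispersion, with the proportional ML line for reference.
#'
#' @param curve Output of [binned_response_curve()].
#' @return A ggplot object.
#' @export
plot_response_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$sigma_mid,
                                      y = .data$mean_response)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(sigma[ML] ~ "(px)"),
                  y = "mean response (px)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.weighting_pattern
#' @export
plot_weighting_pattern <- function(object, ...) {
  autoplot.weighting_pattern(object, ...)
}

#' Plot a weighting pattern
#'
#' Per-participant normalized weights by excentricity rank (grey lines),
#' group medians with bootstrap CIs (points, error bars), and the flat
#' equal-weight line of Gaussian inference.
#'
#' @param object A [weighting_pattern()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weighting_pattern <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$rank, y = .data$median_omega)) +
    ggplot2::geom_line(data = object$by_participant,
                       ggplot2::aes(y = .data$omega,
                                    group = .data$participant_id),
                       colour = "grey75") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.1,
                           colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "excentricity rank", y = "normalized weight") +
    ggplot2::theme_minimal()
}

#' Plot the pairwise model comparison matrix
#'
#' Colour encodes the probability that the row model generated a randomly
#' chosen participant's data against the column model; asterisks mark
#' exceedance probabilities above 0.95 (*) and 0.99 (**).
#'
#' @param object A [pairwise_bms()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bms_pairwise <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col_model,
                                       y = .data$row_model,
                                       fill = .data$r_row)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$significance)) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1),
                                  low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  name = "P(row model)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bms_pairwise
#' @export
plot_pairwise_matrix <- function(object, ...) {
  autoplot.bms_pairwise(object, ...)
}

#' Histogram of sample dispersions
#'
#' Compares the renormalized scheme's flat dispersion histogram with the
#' long-tailed histogram of the unnormalized scheme.
#'
#' @param session Renormalized session tibble.
#' @param unnormalized Optional session from
#'   [generate_unnormalized_session()].
#' @return A ggplot object.
#' @export
plot_sigma_histogram <- function(session, unnormalized = NULL) {
  df <- tibble(sigma = sigma_ml(session_d_matrix(session)),
               scheme = "renormalized")
  if (!is.null(unnormalized)) {
    df <- bind_rows(df, tibble(
      sigma = sigma_ml(session_d_matrix(unnormalized)),
      scheme = "unnormalized"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, fill = .data$scheme)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 40) +
    ggplot2::labs(x = expression(sigma[ML] ~ "(px)"), y = "trials") +
    ggplot2::theme_minimal()
}
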