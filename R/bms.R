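#' Hierarchical group-level Bayesian model selection
#'
#' Treats the model identity of each participant as a draw from a multinomial
#' with unknown frequencies `r`, and estimates a Dirichlet posterior
#' `Dir(r | alpha)` from the per-participant log evidences (CVLLs) by the
#' variational fixed point: responsibilities
#' `u_pm \propto exp(L_pm + psi(alpha_m) - psi(sum(alpha)))`, then
#' `alpha_m = alpha0_m + sum_p u_pm`, iterated to convergence. The prior is
#' the uninformative all-ones Dirichlet.
#'
#' @param evidence Either a numeric matrix (participants x models, column
#'   names = model ids) or a tidy tibble with `participant_id`, `model_id`,
#'   `cvll`.
#' @param alpha0 Dirichlet prior concentrations (default 1 for every model).
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Iteration cap (error if exceeded).
#' @return An object of class `dirichlet_posterior` with fields `alpha`, `r`
#'   (expected model frequencies), `u` (per-participant responsibilities).
#' @export
bms_dirichlet <- function(evidence, alpha0 = NULL, tol = 1e-6,
                          max_iter = 1e4) {
  L <- evidence_matrix(evidence)
  M <- ncol(L)
  P <- nrow(L)
  if (M < 2) abort("need at least 2 models")
  if (is.null(alpha0)) alpha0 <- rep(1, M)
  alpha <- alpha0 + P / M
  if (P == 0) {
    alpha <- alpha0
    u <- matrix(numeric(0), 0, M)
  } else {
    for (it in seq_len(max_iter)) {
      lu <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
      lu <- lu - apply(lu, 1, max)
      u <- exp(lu)
      u <- u / rowSums(u)
      alpha_new <- alpha0 + colSums(u)
      if (max(abs(alpha_new - alpha)) < tol) {
        alpha <- alpha_new
        break
      }
      alpha <- alpha_new
      if (it == max_iter) abort("BMS fixed point did not converge")
    }
  }
  structure(list(alpha = setNames(as.numeric(alpha), colnames(L)),
                 r = setNames(as.numeric(alpha / sum(alpha)), colnames(L)),
                 u = u, alpha0 = alpha0, models = colnames(L),
                 n_participants = P),
            class = "dirichlet_posterior")
}

evidence_matrix <- function(evidence) {
  if (is.matrix(evidence)) {
    if (is.null(colnames(evidence)))
      colnames(evidence) <- paste0("m", seq_len(ncol(evidence)))
    return(evidence)
  }
  wide <- tidyr::pivot_wider(evidence, id_cols = "participant_id",
                             names_from = "model_id", values_from = "cvll")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$participant_id
  m
}

#' Exceedance probability
#'
#' The posterior belief that model `i` is more frequent in the population than
#' its competitors. For two models this is the Beta upper-tail mass beyond
#' 1/2, `P(r_i > 0.5) = 1 - I_0.5(alpha_i, alpha_j)`; for more than two
#' models it is estimated by seeded Monte Carlo over the Dirichlet.
#'
#' @param post A [bms_dirichlet()] posterior.
#' @param model Model id or index (default: all models).
#' @param n_draws Monte-Carlo draws for the general case (default 1e5).
#' @param seed Monte-Carlo seed.
#' @return Probabilities in `[0, 1]`, named by model.
#' @export
exceedance_probability <- function(post, model = NULL, n_draws = 1e5,
                                   seed = 1) {
  stopifnot(inherits(post, "dirichlet_posterior"))
  a <- post$alpha
  M <- length(a)
  p <- if (M == 2) {
    c(pbeta(0.5, a[1], a[2], lower.tail = FALSE),
      pbeta(0.5, a[2], a[1], lower.tail = FALSE))
  } else {
    draws <- with_seed(seed, {
      g <- matrix(rgamma(n_draws * M, shape = rep(a, each = n_draws)),
                  n_draws, M)
      g / rowSums(g)
    })
    win <- apply(draws, 1, which.max)
    tabulate(win, M) / n_draws
  }
  p <- setNames(p, post$models)
  if (!is.null(model)) p[model] else p
}

# significance marks used in the comparison matrix
pexc_stars <- function(p) {
  ifelse(p >= 0.99, "**", ifelse(p >= 0.95, "*", ""))
}

#' Pairwise model comparison matrix
#'
#' Runs the hierarchical model selection separately on every ordered model
#' pair: each cell reports the expected probability `r_row` that the row model
#' generated a randomly chosen participant's data (against the column model),
#' its exceedance probability, and significance marks at 0.95 (*) and
#' 0.99 (**). The matrix is antisymmetric: `r_row(i, j) = 1 - r_row(j, i)`.
#'
#' @param evidence Evidence table (see [bms_dirichlet()]).
#' @return Tibble of class `bms_pairwise` with `row_model`, `col_model`,
#'   `r_row`, `p_exc`, `significance`.
#' @export
pairwise_bms <- function(evidence) {
  L <- evidence_matrix(evidence)
  models <- colnames(L)
  grid <- expand.grid(row_model = models, col_model = models,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$row_model != grid$col_model, ]
  out <- purrr::pmap_dfr(grid, function(row_model, col_model) {
    post <- bms_dirichlet(L[, c(row_model, col_model), drop = FALSE])
    pe <- exceedance_probability(post)[1]
    tibble(row_model = row_model, col_model = col_model,
           r_row = unname(post$r[1]), p_exc = unname(pe),
           significance = pexc_stars(unname(pe)))
  })
  class(out) <- c("bms_pairwise", class(out))
  out
}

#' @export
print.dirichlet_posterior <- function(x, ...) {
  cat(sprintf("<dirichlet_posterior: %d participants, %d models>\n",
              x$n_participants, length(x$alpha)))
  print(round(x$r, 4))
  invisible(x)
}
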