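#' Fitting control parameters
#'
#' The training objective (the lapse-mixture response log-likelihood) is
#' maximized in two stages: a population stage that sweeps `n_global`
#' Latin-hypercube candidates over the model-specific parameters with the
#' mapping coefficients profiled out by least squares, followed by `n_local`
#' Nelder-Mead refinements of the best candidates over all parameters jointly.
#'
#' @param n_global Candidate count of the population stage.
#' @param n_local Number of local refinements started from the best
#'   candidates.
#' @param maxit Iteration cap per Nelder-Mead refinement.
#' @param quadratic Include the quadratic response-mapping term `beta2`
#'   (off by default; kept as a test variant).
#' @param seed Seed for the candidate sweep (fits are bit-reproducible).
#' @param gpr_restarts,gpr_maxit Search budget for the GPR ceiling model
#'   (see [gpr_fit()]).
#' @export
fit_control <- function(n_global = 24, n_local = 2, maxit = 300,
                        quadratic = FALSE, seed = 1, gpr_restarts = 8,
                        gpr_maxit = 150) {
  list(n_global = n_global, n_local = n_local, maxit = maxit,
       quadratic = isTRUE(quadratic), seed = seed,
       gpr_restarts = gpr_restarts, gpr_maxit = gpr_maxit)
}

# run expr under a temporary seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(as.integer(seed))
  expr
}

#' Fit a candidate model to a session
#'
#' Maximizes the training response log-likelihood ([response_loglik()]) over
#' the model's free parameters: the response-mapping coefficients and, where
#' present, the shape exponent `p`, the kernel width factor `a`, or the four
#' excentricity weights. The heteroscedastic noise model is re-estimated from
#' the training residuals at every objective evaluation, so the fitted
#' parameters and their noise model are mutually consistent.
#'
#' @param session Session tibble with responses `y`.
#' @param model_id One of [estimator_catalog()]'s identifiers, or `"gpr"` for
#'   the Gaussian-process ceiling (see [gpr_fit()]).
#' @param control A [fit_control()] list.
#' @param idx Training row indices (default all rows); predictions are still
#'   defined for every trial.
#' @return An object of class `estimator_fit`.
#' @export
fit_estimator <- function(session, model_id, control = fit_control(),
                          idx = NULL) {
  if (!"y" %in% names(session)) abort("session has no responses `y`")
  if (identical(model_id, "gpr"))
    return(gpr_fit(session, idx = idx, seed = control$seed,
                   restarts = control$gpr_restarts,
                   maxit = control$gpr_maxit))
  reg <- est_registry()[[model_id]]
  if (is.null(reg)) abort(paste0("unknown model_id: ", model_id))
  if (is.null(idx)) idx <- seq_len(nrow(session))
  ctx <- estimator_context(session, train_mean_y = mean(session$y[idx]))
  fit_core(ctx, session$y, model_id, reg, control, idx)
}

# shared fitting core; also used with permuted contexts by the permutation test
fit_core <- function(ctx, y, model_id, reg, control, idx, start = NULL,
                     local_only = FALSE) {
  nt <- length(reg$theta_names)
  wgt_like <- reg$beta1_fixed
  quad <- control$quadratic

  # parameter vector layout: [theta..., beta0, (beta1), (beta2)]
  # theta is optimized on a transformed scale: omega = u^2 (wgt),
  # p and a in log-space
  to_internal <- function(theta) {
    if (wgt_like) sqrt(theta) else if (nt > 0) log(theta) else numeric()
  }
  from_internal <- function(u) {
    if (wgt_like) u^2
    else if (nt > 0) pmin(pmax(exp(u), reg$theta_lower), reg$theta_upper)
    else numeric()
  }
  predict_par <- function(par) {
    theta <- from_internal(par[seq_len(nt)])
    S <- reg$S_fun(ctx, theta)
    b <- if (nt > 0) par[-seq_len(nt)] else par
    if (wgt_like) apply_response_mapping(S, b[1], 1, if (quad) b[2] else 0)
    else apply_response_mapping(S, b[1], b[2], if (quad) b[3] else 0)
  }
  objective <- function(par) {
    yhat <- predict_par(par)
    if (any(!is.finite(yhat))) return(1e10)
    noise <- suppressWarnings(bin_thetas(yhat[idx], y[idx]))
    -response_loglik(y[idx], yhat[idx], noise)
  }
  # profile mapping coefficients by OLS for a given theta (population stage)
  profile_beta <- function(theta) {
    S <- reg$S_fun(ctx, theta)[idx]
    if (wgt_like) {
      b0 <- mean(y[idx] - S)
      if (quad) c(b0, 0) else b0
    } else {
      fit <- if (quad) lm(y[idx] ~ S + I(S^2)) else lm(y[idx] ~ S)
      b <- unname(coef(fit))
      b[is.na(b)] <- 0
      b
    }
  }

  # inner refinement of the mapping coefficients at fixed dispersion
  # estimates; the nonlinear parameter (if any) is profiled out above it
  inner_beta <- function(S, bstart) {
    obj_b <- function(b) {
      yhat <- if (wgt_like)
        apply_response_mapping(S, b[1], 1, if (quad) b[2] else 0)
      else apply_response_mapping(S, b[1], b[2], if (quad) b[3] else 0)
      if (any(!is.finite(yhat))) return(1e10)
      noise <- suppressWarnings(bin_thetas(yhat[idx], y[idx]))
      -response_loglik(y[idx], yhat[idx], noise)
    }
    if (length(bstart) == 1) {
      res <- optim(c(bstart, 0), function(b) obj_b(b[1]),
                   method = "Nelder-Mead",
                   control = list(maxit = control$maxit, reltol = 1e-10))
      list(par = res$par[1], value = res$value)
    } else {
      optim(bstart, obj_b, method = "Nelder-Mead",
            control = list(maxit = control$maxit, reltol = 1e-10))
    }
  }

  best <- NULL
  single_theta <- nt == 1 && !wgt_like
  if (nt == 0) {
    # fixed dispersion estimates: compute S once, refine the mapping only
    S <- reg$S_fun(ctx, numeric())
    cand <- list(inner_beta(S, profile_beta(numeric())))
    if (!is.null(start)) cand <- c(cand, list(inner_beta(S, start)))
    best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  } else if (single_theta) {
    # profile likelihood over the (log-scale) nonlinear parameter:
    # population sweep, then Brent refinement in a bracket around the best
    outer_obj <- function(u) {
      theta <- from_internal(u)
      S <- reg$S_fun(ctx, theta)
      res <- inner_beta(S, profile_beta(theta))
      list(value = res$value, beta = res$par)
    }
    lo <- log(reg$theta_lower); hi <- log(reg$theta_upper)
    us <- with_seed(control$seed,
                    lo + as.vector(lhs::randomLHS(control$n_global, 1)) *
                      (hi - lo))
    us <- c(us, log(pmin(pmax(c(p = 2, a = 0.5)[reg$theta_names],
                              reg$theta_lower), reg$theta_upper)))
    if (!is.null(start)) us <- c(start[1], us)
    evals <- lapply(us, outer_obj)
    vals <- vapply(evals, `[[`, numeric(1), "value")
    u0 <- us[which.min(vals)]
    span <- (hi - lo) / max(4, control$n_global / 2)
    memo <- new.env()
    ref <- optimize(function(u) {
      e <- outer_obj(u)
      assign(sprintf("%.12g", u), e, envir = memo)
      e$value
    }, interval = c(max(lo, u0 - span), min(hi, u0 + span)), tol = 1e-5)
    e_best <- get(sprintf("%.12g", ref$minimum), envir = memo)
    cand <- list(list(par = c(ref$minimum, e_best$beta),
                      value = e_best$value),
                 list(par = c(u0, evals[[which.min(vals)]]$beta),
                      value = min(vals)))
    best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  } else {
    starts <- list()
    if (!is.null(start)) starts <- list(start)
    if (!local_only) {
      cand <- with_seed(control$seed, {
        if (nt > 0) {
          U <- lhs::randomLHS(control$n_global, nt)
          lapply(seq_len(control$n_global), function(i) {
            th <- U[i, ] * 8
            c(to_internal(th), profile_beta(th))
          })
        } else {
          list(profile_beta(numeric()))
        }
      })
      # neutral start: unit weights (wgt) or plain OLS mapping
      neutral <- if (wgt_like) rep(1, 4) else numeric()
      cand <- c(cand, list(c(to_internal(neutral), profile_beta(neutral))))
      vals <- vapply(cand, objective, numeric(1))
      ord <- order(vals)
      starts <- c(starts,
                  cand[ord[seq_len(min(control$n_local, length(cand)))]])
    }
    for (s in starts) {
      res <- tryCatch(
        optim(s, objective, method = "Nelder-Mead",
              control = list(maxit = control$maxit, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best)) {
      warn("optimization failed; returning best population candidate")
      s <- starts[[1]]
      best <- list(par = s, value = objective(s))
    }
  }

  par <- best$par
  theta <- from_internal(par[seq_len(nt)])
  names(theta) <- reg$theta_names
  b <- if (nt > 0) par[-seq_len(nt)] else par
  beta <- if (wgt_like) c(beta0 = unname(b[1]), beta1 = 1)
  else c(beta0 = unname(b[1]), beta1 = unname(b[2]))
  if (quad) beta <- c(beta, beta2 = unname(b[length(b)]))
  yhat <- predict_par(par)
  noise <- suppressWarnings(bin_thetas(yhat[idx], y[idx]))
  structure(list(
    model_id = model_id,
    beta = beta,
    theta = theta,
    omega_normalized = if (wgt_like) normalize_weights(theta) else NULL,
    noise = noise,
    train_ll = -best$value,
    n_train = length(idx),
    train_idx = idx,
    train_mean_y = ctx$train_mean_y,
    fitted = yhat,
    control = control
  ), class = "estimator_fit")
}

#' @rdname fit_estimator
#' @param object An `estimator_fit`.
#' @param newdata A session tibble to predict for (default: the fitted
#'   values of the training session).
#' @param ... Unused.
#' @export
predict.estimator_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  reg <- est_registry()[[object$model_id]]
  ctx <- estimator_context(newdata, train_mean_y = object$train_mean_y)
  S <- reg$S_fun(ctx, unname(object$theta))
  b2 <- if ("beta2" %in% names(object$beta)) object$beta[["beta2"]] else 0
  apply_response_mapping(S, object$beta[["beta0"]], object$beta[["beta1"]], b2)
}

#' @export
print.estimator_fit <- function(x, ...) {
  cat(sprintf("<estimator_fit: %s, train logLik %.2f on %d trials>\n",
              x$model_id, x$train_ll, x$n_train))
  co <- c(x$beta, x$theta)
  cat("  ", paste(sprintf("%s = %.4g", names(co), co), collapse = ", "), "\n")
  invisible(x)
}
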