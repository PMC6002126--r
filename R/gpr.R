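#' Gaussian process regression predictability ceiling
#'
#' A low-bias functional approximation from the (excentricity-sorted) sample
#' to the response, used as an upper bound on the predictable structure in
#' behaviour. The squared-exponential kernel
#' `k(di, dj) = theta * exp(-0.5 * sum_n (din - djn)^2 / sigma_n^2)` defines
#' similarity between trials; predictions are the GP posterior mean
#' `k^T C^-1 y` with `C = K + sigma_I^2 I`.
#'
#' @param di,dj Numeric input vectors (one trial each, sorted ascending by
#'   excentricity).
#' @param hp Hyperparameter list/vector: `theta`, `sigma` (length-N length
#'   scales), `sigma_I`.
#' @export
gpr_kernel <- function(di, dj, hp) {
  hp <- as_gpr_hp(hp, length(di))
  hp$theta * exp(-0.5 * sum((di - dj)^2 / hp$sigma^2))
}

as_gpr_hp <- function(hp, n_dim) {
  if (!is.list(hp)) {
    stopifnot(length(hp) == n_dim + 2)
    hp <- list(theta = hp[1], sigma = hp[2:(n_dim + 1)],
               sigma_I = hp[n_dim + 2])
  }
  if (any(unlist(hp) <= 0)) abort("GPR hyperparameters must be positive")
  hp
}

# kernel matrix between row sets
gpr_kmat <- function(X1, X2, hp) {
  D2 <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(ncol(X1)))
    D2 <- D2 + outer(X1[, j], X2[, j], "-")^2 / hp$sigma[j]^2
  hp$theta * exp(-0.5 * D2)
}

# Cholesky with adaptive jitter
gpr_chol <- function(C, theta) {
  jit <- 1e-8 * theta
  for (i in 1:8) {
    R <- tryCatch(chol(C + diag(jit * (i > 1), nrow(C))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- jit * 10
  }
  abort("covariance matrix not positive definite even with jitter")
}

#' @rdname gpr_kernel
#' @param X_train,y_train Training inputs (rows) and responses.
#' @param X_new Inputs to predict for.
#' @param return_var Also return the predictive variance (kernel variance
#'   minus the explained part, plus intrinsic noise).
#' @return `gpr_predict_raw()`: posterior-mean predictions (or a list with
#'   `mean` and `var` when `return_var = TRUE`).
#' @export
gpr_predict_raw <- function(X_train, y_train, hp, X_new,
                            return_var = FALSE) {
  hp <- as_gpr_hp(hp, ncol(X_train))
  C <- gpr_kmat(X_train, X_train, hp) + diag(hp$sigma_I^2, nrow(X_train))
  R <- gpr_chol(C, hp$theta)
  alpha <- backsolve(R, forwardsolve(t(R), y_train))
  Kx <- gpr_kmat(X_new, X_train, hp)
  mu <- as.vector(Kx %*% alpha)
  if (!return_var) return(mu)
  V <- forwardsolve(t(R), t(Kx))
  v <- pmax(hp$theta - colSums(V^2), 0) + hp$sigma_I^2
  list(mean = mu, var = v)
}

#' Fit the GPR ceiling model
#'
#' Hyperparameters `(theta, sigma_1..sigma_N, sigma_I)` are chosen to minimize
#' the generalization error: the mean held-out negative log response
#' likelihood (lapse-mixture, noise bins from the inner training folds) of an
#' inner k-fold cross validation. This inner CV is part of training; model
#' comparison wraps the fitted GPR in the same outer CV as every other model.
#' The search is multi-start Nelder-Mead in log hyperparameter space.
#'
#' @param session Session tibble with responses.
#' @param inner_folds Inner CV folds (default 5).
#' @param restarts Random restarts of the local search (default 8).
#' @param seed Seed for restarts and inner splits.
#' @param idx Training row indices (default all).
#' @param maxit Nelder-Mead iteration cap per restart.
#' @return An object of class `gpr_fit` (usable with `predict()`).
#' @export
gpr_fit <- function(session, inner_folds = 5, restarts = 8, seed = 1,
                    idx = NULL, maxit = 150) {
  if (is.null(idx)) idx <- seq_len(nrow(session))
  X <- excentricity_matrix(session_d_matrix(session))[idx, , drop = FALSE]
  y_raw <- session$y[idx]
  y_center <- mean(y_raw)
  y <- y_raw - y_center          # GP prior mean zero: model deviations
  n_dim <- ncol(X)
  splits <- stratified_cv_splits(y, k = inner_folds, repeats = 1,
                                 n_strata = min(8, length(y) %/% inner_folds),
                                 seed = seed)
  # hyperparameter objective: held-out Gaussian predictive log-likelihood
  # (the GP's own predictive variance identifies sigma_I; the shared
  # lapse-mixture likelihood is used only for cross-model scoring)
  objective <- function(logpar) {
    hp <- as_gpr_hp(exp(logpar), n_dim)
    ll <- vapply(seq_len(inner_folds), function(f) {
      test <- splits$trial[splits$fold == f]
      train <- setdiff(seq_along(y), test)
      pred <- tryCatch(
        gpr_predict_raw(X[train, , drop = FALSE], y[train], hp,
                        X[test, , drop = FALSE], return_var = TRUE),
        error = function(e) NULL)
      if (is.null(pred)) return(-1e8)
      sum(dnorm(y[test], pred$mean, sqrt(pred$var), log = TRUE))
    }, numeric(1))
    -mean(ll)
  }
  sy <- sd(y)
  base <- log(c(sy^2, rep(diff(range(X)) / 2, n_dim), sy / 2))
  res <- with_seed(seed, {
    starts <- lapply(seq_len(restarts), function(i) {
      if (i == 1) base else base + rnorm(length(base), 0, 1)
    })
    best <- NULL
    for (s in starts) {
      r <- tryCatch(optim(s, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-8)),
                    error = function(e) NULL)
      if (is.null(r)) next
      if (is.null(best) || r$value < best$value) best <- r
    }
    if (is.null(best)) {
      warn("GPR optimizer failed on all restarts; using the base start")
      best <- list(par = base, value = objective(base))
    }
    best
  })
  hp <- as_gpr_hp(exp(res$par), n_dim)
  fitted_all <- gpr_predict_raw(X, y, hp, X) + y_center
  # noise bins from inner out-of-fold predictions: in-sample GP predictions
  # partially interpolate and would understate the response variability
  oof <- numeric(length(y))
  for (f in seq_len(inner_folds)) {
    test <- splits$trial[splits$fold == f]
    train <- setdiff(seq_along(y), test)
    oof[test] <- gpr_predict_raw(X[train, , drop = FALSE], y[train], hp,
                                 X[test, , drop = FALSE]) + y_center
  }
  noise <- suppressWarnings(bin_thetas(oof, y_raw))
  structure(list(model_id = "gpr", hp = hp, X = X, y = y,
                 y_center = y_center,
                 inner_objective = -res$value, noise = noise,
                 fitted = fitted_all, train_idx = idx, n_train = length(idx)),
            class = "gpr_fit")
}

#' @rdname gpr_fit
#' @param object A `gpr_fit`.
#' @param newdata Session tibble to predict for.
#' @param ... Unused.
#' @export
predict.gpr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  Xn <- excentricity_matrix(session_d_matrix(newdata))
  gpr_predict_raw(object$X, object$y, object$hp, Xn) + object$y_center
}

#' @export
print.gpr_fit <- function(x, ...) {
  cat(sprintf(
    "<gpr_fit: %d trials, theta %.3g, length scales [%s] px, sigma_I %.3g>\n",
    x$n_train, x$hp$theta,
    paste(sprintf("%.1f", x$hp$sigma), collapse = ", "), x$hp$sigma_I))
  invisible(x)
}
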