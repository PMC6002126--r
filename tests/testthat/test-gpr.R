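test_that("the GPR kernel is a symmetric similarity measure", {
  hp <- list(theta = 4, sigma = rep(2, 4), sigma_I = 1)
  expect_equal(gpr_kernel(1:4, 1:4, hp), 4)
  expect_equal(gpr_kernel(1:4, 2:5, hp), gpr_kernel(2:5, 1:4, hp))
  expect_lt(gpr_kernel(1:4, 1:4 + 100, hp), 1e-10)
  expect_error(gpr_kernel(1:4, 1:4, list(theta = -1, sigma = rep(2, 4),
                                         sigma_I = 1)), "positive")
})

test_that("GPR predictions interpolate and revert to the prior mean", {
  X <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  hp <- list(theta = 4, sigma = rep(2, 4), sigma_I = 1e-9)
  expect_equal(gpr_predict_raw(X, c(10, 20), hp, X), c(10, 20),
               tolerance = 1e-6)
  # far from all training points the prediction decays to zero
  expect_lt(abs(gpr_predict_raw(X, c(10, 20), hp,
                                matrix(1e3, 1, 4))), 1e-8)
  # midway between two symmetric points: the mean of their targets
  X2 <- rbind(c(0, 0, 0, 0), c(2, 2, 2, 2))
  mid <- matrix(1, 1, 4)
  k <- hp$theta * exp(-0.5 * 4 / 4)
  C <- hp$theta * diag(2)
  C[1, 2] <- C[2, 1] <- hp$theta * exp(-0.5 * 16 / 4)
  oracle <- as.numeric(c(k, k) %*% solve(C, c(10, 30)))
  expect_equal(gpr_predict_raw(X2, c(10, 30), hp, mid), oracle,
               tolerance = 1e-8)
  expect_equal(oracle, mean(c(10, 30)) * 2 * k / (hp$theta + C[1, 2]))
})

test_that("GPR learns near-deterministic behaviour to high accuracy", {
  p <- simulate_participant("nm", params = list(beta0 = 0, beta1 = 1),
                            noise = c(0.1, 0), lapse_rate = 0,
                            n_trials = 60, seed = 31, feedback = FALSE)
  g <- gpr_fit(p, restarts = 3, maxit = 60, seed = 1)
  pred <- predict(g, p)
  expect_gt(cor(pred, p$y), 0.995)
})

test_that("the intrinsic noise hyperparameter recovers the true noise SD", {
  s_true <- 8
  p <- simulate_participant("nm", noise = c(s_true, 0), lapse_rate = 0,
                            n_trials = 200, seed = 32, feedback = FALSE)
  g <- gpr_fit(p, restarts = 4, maxit = 80, seed = 2)
  expect_lt(abs(g$hp$sigma_I - s_true) / s_true, 0.25)
})

test_that("GPR predicts close to the true generator's level per trial", {
  # the low-bias ceiling cannot beat the true parametric model on data that
  # model generated, but its held-out log-likelihood should come close on a
  # per-trial basis (the flexible kernel costs a small estimation-variance
  # premium over the 2-parameter truth)
  p <- simulate_participant("nm", seed = 33, n_trials = 200,
                            feedback = FALSE)
  sp <- stratified_cv_splits(p$y, repeats = 1, seed = 3)
  ctl <- fit_control(n_global = 6, gpr_restarts = 3, gpr_maxit = 100)
  cv_gpr <- cv_log_likelihood(p, "gpr", sp, control = ctl)
  cv_nm <- cv_log_likelihood(p, "nm", sp, control = ctl)
  per_trial_gap <- (cv_gpr - cv_nm) / 40    # 40 held-out trials per fold
  expect_gt(per_trial_gap, -0.25)
})
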