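test_that("near-noiseless normal-model data is identified exactly", {
  p <- simulate_participant("nm", params = list(beta0 = 5, beta1 = 0.8),
                            noise = c(1e-3, 0), lapse_rate = 0,
                            n_trials = 80, seed = 21, feedback = FALSE)
  f <- fit_estimator(p, "nm", control = quick_ctl)
  expect_lt(abs(f$beta[["beta0"]] - 5), 1e-3)
  expect_lt(abs(f$beta[["beta1"]] - 0.8), 1e-3)
})

test_that("a single-point weighting heuristic is recovered", {
  p <- low_noise_participant("wgt", n_trials = 320, seed = 22,
                             params = list(beta0 = 0,
                                           omega = c(0, 4, 0, 0)))
  f <- fit_estimator(p, "wgt", control = quick_ctl)
  expect_true(all(abs(f$omega_normalized - c(0, 4, 0, 0)) < 0.5))
  expect_equal(unname(which.max(f$omega_normalized)), 2L)
})

test_that("refits under the same control are bit-identical", {
  p <- simulate_participant("gnm", seed = 23, n_trials = 100,
                            feedback = FALSE)
  f1 <- fit_estimator(p, "gnm", control = quick_ctl)
  f2 <- fit_estimator(p, "gnm", control = quick_ctl)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$theta, f2$theta)
})

test_that("the population stage matches a dense random-search oracle", {
  # contract for the global stage: profile objective within 1% of a
  # 1e4-point random search over the nonlinear parameter
  p <- simulate_participant("gnm", seed = 29, n_trials = 100,
                            feedback = FALSE)
  f <- fit_estimator(p, "gnm", control = quick_ctl)
  obj <- function(pp) {
    S <- s_gnorm(d_matrix(p), pp)
    co <- coef(lm(p$y ~ S))
    yhat <- co[1] + co[2] * S
    nm <- suppressWarnings(bin_thetas(yhat, p$y))
    response_loglik(p$y, yhat, nm)
  }
  set.seed(30)
  oracle <- max(vapply(exp(runif(1e4, log(0.1), log(50))), obj, numeric(1)))
  expect_gt(f$train_ll, oracle - 0.01 * abs(oracle))
})

test_that("stratified splits balance the target across folds", {
  set.seed(24)
  y <- runif(320, 10, 140)
  sp <- stratified_cv_splits(y, seed = 1)
  expect_equal(nrow(sp), 640)              # two repeats cover every trial
  counts <- dplyr::count(sp, rep, fold)
  expect_true(all(counts$n == 64))
  for (r in 1:2) {
    test_union <- sort(sp$trial[sp$rep == r])
    expect_equal(test_union, 1:320)        # partition per repeat
    fold_means <- tapply(y[sp$trial[sp$rep == r]],
                         sp$fold[sp$rep == r], mean)
    expect_true(all(abs(fold_means / mean(y) - 1) < 0.05))
  }
})

test_that("held-out responses never influence fitted parameters", {
  p <- simulate_participant("nm", seed = 25, n_trials = 100,
                            feedback = FALSE)
  train <- 1:80
  f1 <- fit_estimator(p, "nm", control = quick_ctl, idx = train)
  p2 <- p
  p2$y[81:100] <- p2$y[81:100] + 50
  f2 <- fit_estimator(p2, "nm", control = quick_ctl, idx = train)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$noise$theta, f2$noise$theta)
})

test_that("deciban conversion follows its definition", {
  expect_equal(dhart_diff(log(10), 0), 10)
  expect_equal(dhart_diff(2, 2), 0)
  expect_equal(dhart_diff(1, 3), -dhart_diff(3, 1))
  expect_equal(as.character(dhart_label(25)), "decisive")
  expect_equal(as.character(dhart_label(-3)), "barely worth mentioning")
})

test_that("the baseline wins on stimulus-independent responses", {
  p <- simulate_participant("nm", seed = 26, n_trials = 160,
                            feedback = FALSE)
  set.seed(27)
  p$y <- runif(160, 30, 120)               # responses ignore the stimulus
  sp <- stratified_cv_splits(p$y, repeats = 1, seed = 2)
  cv_base <- cv_log_likelihood(p, "baseline", sp, control = quick_ctl)
  cv_nm <- cv_log_likelihood(p, "nm", sp, control = quick_ctl)
  expect_gt(cv_base, cv_nm - 3)
})

test_that("permutation test flags informative weights only", {
  p <- low_noise_participant("wgt", n_trials = 120, seed = 28,
                             params = list(beta0 = 0,
                                           omega = c(0, 0, 4, 0)))
  res <- suppressWarnings(
    weight_permutation_test(p, n_perm = 40, control = quick_ctl, seed = 5))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(res$significant[3])
  expect_lt(sum(res$significant[-3]), 2)
  expect_warning(weight_permutation_test(p, n_perm = 20,
                                         control = quick_ctl, seed = 5),
                 "unstable")
})
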