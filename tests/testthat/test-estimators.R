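test_that("heuristic estimators compute the stated sample statistics", {
  d <- c(1, -5, 2, 0)
  expect_equal(s_max(d), 5)
  expect_equal(s_range(d), 7)
  expect_equal(s_range(c(-3, 3, -3, 3)), 2 * s_max(c(-3, 3, -3, 3)))
  expect_equal(s_gnorm(c(0, 0, 0, 8), p = 1), 2)   # (1/4 * 8)^1
  expect_equal(s_gnorm(d, 2), sqrt(2) * sigma_ml(d))
  expect_lt(abs(s_gnorm(d, 45) - s_max(d)) / s_max(d), 0.08)
  expect_error(s_gnorm(d, 0), "positive")
})

test_that("the weighting estimator generalizes the ML dispersion", {
  D <- random_samples(25, seed = 2)
  expect_equal(s_weighting(D, rep(1, 4)), sigma_ml(D))
  # single-point heuristic: all mass on one excentricity rank
  d <- c(1, -2, 3, -4)                      # excentricities 1..4
  expect_equal(s_weighting(d, c(0, 0, 4, 0)), 3)
  expect_error(s_weighting(d, c(-1, 1, 1, 1)), "nonnegative")
  expect_equal(normalize_weights(c(2, 2, 0, 0)), c(2, 2, 0, 0))
  expect_equal(normalize_weights(c(1, 1, 1, 5)), c(0.5, 0.5, 0.5, 2.5))
})

test_that("the response mapping is affine with an optional quadratic term", {
  expect_equal(apply_response_mapping(10, 0, 1), 10)
  expect_equal(apply_response_mapping(10, 5, 0.5), 10)
  expect_equal(apply_response_mapping(10, 1, 1, 0.1), 21)
})

test_that("the KDE response solves the capture equation for its mixture", {
  # symmetric worked case: equal-weight kernels at +-10 with width 10
  d <- c(-10, -10, 10, 10)
  y <- kde_response(d, a = 1)
  oracle <- uniroot(function(z)
    pnorm((z - 10) / 10) + pnorm((z + 10) / 10) - 1 - 0.65,
    c(0, 100), tol = 1e-12)$root
  expect_lt(abs(y - oracle), 1e-6)
  # self-consistency on random samples
  D <- random_samples(20, seed = 3)
  ys <- kde_response(D, a = 0.7)
  for (i in seq_len(nrow(D))) {
    md <- kde_predictive(D[i, ], a = 0.7)
    expect_lt(abs(capture_probability(md, ys[i]) - 0.65), 1e-8)
  }
})

test_that("KDE converges to the third most excentric point as a -> 0", {
  D <- random_samples(30, seed = 4)
  expect_lt(max(abs(kde_response(D, a = 1e-6) - delta_kde_response(D))),
            1e-4)
  expect_equal(delta_kde_response(c(1, -2, 3, -4)), 3)
  expect_equal(delta_kde_response(c(5, 5, 5, 5)), 5)
})

test_that("the KDE response varies continuously and widens with the kernel", {
  D <- random_samples(100, seed = 5)
  as <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  Y <- sapply(as, function(a) kde_response(D, a))
  # wide kernels always yield a wider frame than near-delta kernels; strict
  # monotonicity over the whole width range does not hold in general (a tight
  # central cluster plus an outlying pair lets the frame shrink below |d_(3)|
  # at intermediate widths) but the response grows without bound eventually
  expect_true(all(Y[, length(as)] > Y[, 1]))
  expect_true(all(sapply(seq_len(nrow(D)), function(i)
    kde_response(D[i, ], 5) > kde_response(D[i, ], 1.6))))
  # continuity: small change in a moves the response only slightly
  expect_lt(max(abs(kde_response(D, 0.4) - kde_response(D, 0.401))), 0.5)
})

test_that("the tiling density places sorted points at mid-bin quantiles", {
  d <- c(-3, -1, 1, 3)
  md <- tiling_density(d)
  expect_equal(cdf_at(md, sort(d)), c(0.125, 0.375, 0.625, 0.875))
  expect_lt(abs(cdf_at(md, 10) - 1), 1e-12)
  expect_lt(abs(tiling_response(d) - 2.6), 1e-9)
  expect_warning(tiling_density(c(1, 1, 2, 3)), "coincident")
})

test_that("tiling responses reinsert into their capture integral", {
  D <- random_samples(25, seed = 6)
  ys <- tiling_response(D)
  for (i in seq_len(nrow(D))) {
    md <- tiling_density(D[i, ])
    expect_lt(abs(capture_probability(md, ys[i]) - 0.65), 1e-8)
  }
})

test_that("all stimulus-driven estimators are scale-equivariant", {
  D <- random_samples(40, seed = 7)
  k <- 2.7
  expect_equal(s_max(k * D), k * s_max(D))
  expect_equal(s_range(k * D), k * s_range(D))
  expect_equal(s_weighting(k * D, c(1, 2, 0.5, 0.5)),
               k * s_weighting(D, c(1, 2, 0.5, 0.5)))
  expect_equal(s_gnorm(k * D, 1.3), k * s_gnorm(D, 1.3))
  expect_equal(delta_kde_response(k * D), k * delta_kde_response(D))
  expect_equal(kde_response(k * D, 0.6), k * kde_response(D, 0.6),
               tolerance = 1e-6)
  expect_equal(tiling_response(k * D), k * tiling_response(D),
               tolerance = 1e-9)
  expect_true(all(s_max(D) >= 0 & s_range(D) >= 0 & s_gnorm(D, 1.5) >= 0))
})

test_that("history regressors lag the session with mean imputation", {
  expect_equal(s_baseline(c(10, 20, 30)), 20)
  ses <- tibble::tibble(participant_id = "a", trial = 1:3,
                        d1 = 1, d2 = 2, d3 = 3, d4 = 4, nu = 2.74,
                        y = c(5, 7, 9))
  expect_equal(s_prev_response(ses), c(7, 5, 7))
  expect_equal(s_prev_response(ses, fill = 0), c(0, 5, 7))
  fb <- simulate_participant("nm", seed = 6, n_trials = 15)
  reg <- s_prev_feedback(fb)
  bc <- fb$block_c[!duplicated(fb$block)]
  expect_equal(reg[6:10], rep(bc[1], 5))
  expect_equal(reg[11:15], rep(bc[2], 5))
  expect_equal(reg[1:5], rep(mean(bc[1:2]), 5))
})
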