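test_that("the sigma posterior peaks at the ML dispersion under a flat prior", {
  post <- posterior_sigma(c(75, 75, 75, 75))
  expect_lt(abs(post$mode - 75), 1)
  expect_true(all(post$sigma_grid <= 140))
  expect_equal(sum(post$weights), 1)
  # scale equivariance of the mode within the prior support
  p1 <- posterior_sigma(c(10, -20, 15, -5))
  p2 <- posterior_sigma(2 * c(10, -20, 15, -5))
  expect_lt(abs(p2$mode / p1$mode - 2), 0.01)
  expect_true(posterior_sigma(c(0, 0, 0, 0))$degenerate)
})

test_that("the predictive density is a proper zero-centred scale mixture", {
  post <- posterior_sigma(c(30, -40, 20, -10))
  pd <- predictive_density(post)
  x <- seq(-600, 600, length.out = 4001)
  mass <- sum(density_at(pd, x)) * diff(x)[1]
  expect_lt(abs(mass - 1), 1e-6)
  expect_equal(density_at(pd, 25), density_at(pd, -25))
  expect_true(all(density_at(pd, c(10, 50, 100)) <= density_at(pd, 0)))
  # degenerate posterior reduces to a single Gaussian
  single <- mixture_density("gaussian", means = 0, sds = 7)
  expect_equal(density_at(single, 3), dnorm(3, 0, 7))
})

test_that("capture probability behaves like a CDF of the symmetric frame", {
  pd <- predictive_density(posterior_sigma(c(30, -40, 20, -10)))
  expect_equal(capture_probability(pd, 0), 0)
  expect_gt(capture_probability(pd, 1000), 1 - 1e-6)
  z <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(capture_probability(pd, z)) > 0))
  expect_error(capture_probability(pd, -1), "nonnegative")
  # single-Gaussian check against the standard normal central interval
  single <- mixture_density("gaussian", means = 0, sds = 1)
  z65 <- qnorm(0.5 + 0.65 / 2)
  expect_lt(abs(capture_probability(single, z65) - 0.65), 1e-12)
})

test_that("solve_response inverts the capture probability", {
  single <- mixture_density("gaussian", means = 0, sds = 12)
  z65 <- qnorm(0.5 + 0.65 / 2)
  expect_lt(abs(solve_response(single) - 12 * z65), 1e-6)
  expect_lt(solve_response(single, target = 0.5), solve_response(single))
  pd <- predictive_density(posterior_sigma(c(30, -40, 20, -10)))
  y <- solve_response(pd)
  expect_lt(abs(capture_probability(pd, y) - 0.65), 1e-8)
})

test_that("feedback scores responses against the benchmark", {
  pd <- predictive_density(posterior_sigma(c(30, -40, 20, -10)))
  y <- solve_response(pd)
  fb <- trial_feedback(pd, y)
  expect_lt(abs(fb$c - 0.65), 1e-8)
  expect_lt(fb$delta, 1e-10)
  fb2 <- trial_feedback(pd, solve_response(pd, target = 0.75))
  expect_lt(abs(fb2$delta - 10), 1e-4)
  expect_equal(block_feedback(data.frame(c = rep(0.65, 5),
                                         delta = c(0, 10, 0, 10, 0)))$delta, 4)
})

test_that("benchmark responses depend on the sample only via sigma_ml", {
  s1 <- tibble::tibble(participant_id = "a", trial = 1:2,
                       d1 = c(50, 30), d2 = c(50, -40), d3 = c(-50, 20),
                       d4 = c(-50, 10), nu = c(50, sigma_ml(c(30, -40, 20, 10))))
  # second sample rescaled to sigma_ml 50 must yield the first's response
  f <- 50 / sigma_ml(c(30, -40, 20, 10))
  s1[2, c("d1", "d2", "d3", "d4")] <- as.list(f * c(30, -40, 20, 10))
  out <- benchmark_response(s1)
  expect_lt(abs(out$y_benchmark[1] - out$y_benchmark[2]), 1e-6)
})

test_that("the benchmark biases responses toward intermediate dispersions", {
  z65 <- qnorm(0.5 + 0.65 / 2)
  mk <- function(sml) tibble::tibble(participant_id = "a", trial = 1L,
                                     d1 = sml, d2 = sml, d3 = -sml, d4 = -sml,
                                     nu = sml)
  y_small <- benchmark_response(mk(15))$y_benchmark
  y_large <- benchmark_response(mk(130))$y_benchmark
  expect_gt(y_small, z65 * 15)   # pulled up at the low end
  expect_lt(y_large, z65 * 130)  # pulled down at the high end
})

test_that("add_feedback attaches per-trial and block feedback", {
  s <- simulate_participant("nm", seed = 2, n_trials = 20, feedback = FALSE)
  s <- add_feedback(s)
  expect_true(all(c("c", "delta", "block", "block_c", "block_delta")
                  %in% names(s)))
  expect_equal(max(s$block), 4)
  expect_equal(unique(s$block_delta[s$block == 1]),
               mean(s$delta[s$block == 1]))
  expect_true(all(abs(s$delta - (s$c - 0.65)^2 * 1000) < 1e-12))
})
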