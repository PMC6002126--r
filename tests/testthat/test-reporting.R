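test_that("binned response curves track a noiseless proportional agent", {
  p <- simulate_participant("nm", params = list(beta0 = 0, beta1 = 1),
                            noise = c(1e-9, 0), lapse_rate = 0,
                            n_trials = 200, seed = 71, feedback = FALSE)
  curve <- binned_response_curve(p, n_boot = 200)
  expect_true(all(diff(curve$mean_response) > 0))
  co <- coef(lm(mean_response ~ sigma_mid, data = curve))
  expect_lt(abs(co[2] - 1), 0.05)
  expect_lt(abs(co[1]), 5)
  expect_error(binned_response_curve(p[1:5, ]), "fewer")
})

test_that("capture analysis scores compliance and split-half stability", {
  ideal <- simulate_participant("benchmark", noise = c(1e-12, 0),
                                lapse_rate = 0, n_trials = 40, seed = 72)
  ca <- capture_analysis(ideal)
  expect_lt(abs(ca$by_participant$median_c - 0.65), 1e-6)
  expect_lt(ca$by_participant$median_abs_dev, 1e-6)
  # stationary cohort: no significant first/second-half difference
  ch <- purrr::map_dfr(1:6, function(i)
    simulate_participant("nm", seed = 100 + i, n_trials = 60,
                         participant_id = paste0("s", i)))
  expect_gt(capture_analysis(ch)$split_half_p, 0.05)
  # a late drift is detected
  drift <- ch %>% dplyr::group_by(participant_id) %>%
    dplyr::mutate(y = ifelse(trial <= 30, y * 1.4, y)) %>%
    dplyr::ungroup()
  drift <- add_feedback(dplyr::select(drift, -c, -delta, -block,
                                      -block_c, -block_delta))
  expect_lt(capture_analysis(drift)$split_half_p, 0.05)
})

test_that("surrogate weighting patterns separate the generator classes", {
  ch <- purrr::map_dfr(1:4, function(i)
    low_noise_participant("nm", n_trials = 120, seed = 200 + i) %>%
      dplyr::mutate(participant_id = paste0("s", i)))
  flat <- surrogate_weighting_refit(ch, "nm", control = quick_ctl,
                                    n_boot = 200)
  expect_true(all(abs(flat$summary$median_omega - 1) < 0.25))
  peaked <- surrogate_weighting_refit(ch, "max", control = quick_ctl,
                                      n_boot = 200)
  expect_gt(peaked$summary$median_omega[4], 2.5)
  # delta-KDE-like behaviour elevates the third excentricity rank
  ch3 <- purrr::map_dfr(1:4, function(i)
    low_noise_participant("delta_kde", n_trials = 120, seed = 300 + i) %>%
      dplyr::mutate(participant_id = paste0("s", i)))
  wp <- weighting_pattern(ch3, control = quick_ctl, n_boot = 200)
  expect_equal(which.max(wp$summary$median_omega), 3)
})

test_that("normalized slopes identify the generalization regime", {
  nm_agent <- simulate_participant("nm", params = list(beta0 = 0, beta1 = 1),
                                   noise = c(1e-9, 0), lapse_rate = 0,
                                   n_trials = 100, seed = 73,
                                   feedback = FALSE)
  expect_lt(abs(normalized_slope_analysis(nm_agent)$slope), 1e-6)
  dk <- simulate_participant("delta_kde",
                             params = list(beta0 = 0, beta1 = 1),
                             noise = c(1e-9, 0), lapse_rate = 0,
                             n_trials = 100, seed = 74, feedback = FALSE)
  expect_lt(abs(normalized_slope_analysis(dk)$slope - 1), 1e-6)
  # over the width range typical of fitted behaviour the slope decreases
  # with the kernel width (at very large widths the frame scales with the
  # kernel itself and the relation flattens out)
  slopes <- vapply(c(0.2, 0.4, 0.8), function(a) {
    p <- simulate_participant("kde",
                              params = list(beta0 = 0, beta1 = 1, a = a),
                              noise = c(1e-9, 0), lapse_rate = 0,
                              n_trials = 100, seed = 75, feedback = FALSE)
    normalized_slope_analysis(p)$slope
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("mode counting merges overlapping kernels", {
  d <- c(-30, -10, 10, 30)
  expect_equal(count_modes(kde_predictive(d, a = 0.01)), 4)
  expect_equal(count_modes(kde_predictive(d, a = 5)), 1)
  # equal pair at +-sigma separation merges into one mode
  pair <- mixture_density("gaussian", means = c(-10, 10), sds = c(10, 10))
  expect_equal(count_modes(pair), 1)
  # mode count is nonincreasing in the kernel width
  D <- random_samples(20, seed = 76)
  for (i in seq_len(nrow(D))) {
    if (kde_width(D[i, ], 1) == 0) next
    counts <- vapply(c(0.02, 0.1, 0.3, 0.8, 2),
                     function(a) count_modes(kde_predictive(D[i, ], a)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("exclusion flags stimulus-independent participants", {
  good <- purrr::map_dfr(1:5, function(i)
    simulate_participant("nm", seed = 400 + i, n_trials = 80,
                         participant_id = paste0("g", i),
                         feedback = FALSE))
  bad <- purrr::map_dfr(1:3, function(i) {
    p <- simulate_participant("nm", seed = 500 + i, n_trials = 80,
                              participant_id = paste0("b", i),
                              feedback = FALSE)
    set.seed(600 + i)
    p$y <- sample(p$y)   # shuffle: destroy stimulus dependence
    p
  })
  flags <- exclusion_filter(dplyr::bind_rows(good, bad))
  expect_equal(sum(!flags$included), 3)
  expect_true(all(flags$included[startsWith(flags$participant_id, "g")]))
})

test_that("plot builders return ggplot objects", {
  p <- simulate_participant("nm", seed = 77, n_trials = 60,
                            feedback = FALSE)
  expect_s3_class(plot_response_curve(binned_response_curve(p, n_boot = 50)),
                  "ggplot")
  L <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("nm", "kde")))
  expect_s3_class(autoplot(pairwise_bms(L)), "ggplot")
  expect_s3_class(plot_sigma_histogram(p), "ggplot")
})
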