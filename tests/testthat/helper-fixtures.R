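# shared fixtures: small synthetic sessions and a fast search budget

quick_ctl <- fit_control(n_global = 6, n_local = 1, maxit = 200)

# low-noise participant for recovery checks
low_noise_participant <- function(model_id, n_trials = 120, seed = 1,
                                  params = NULL) {
  simulate_participant(model_id, params = params, noise = c(0.5, 0.01),
                       lapse_rate = 0, n_trials = n_trials, seed = seed,
                       feedback = FALSE)
}

# a handful of random 4-point samples for property checks
random_samples <- function(n, seed = 1, scale = 50) {
  with_seed <- get("with_seed", asNamespace("dispersim"))
  with_seed(seed, matrix(rnorm(4 * n, sd = scale), n, 4))
}

# direct access to internal helpers used by property tests
d_matrix <- function(session) {
  as.matrix(session[grep("^d[0-9]+$", names(session))])
}
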