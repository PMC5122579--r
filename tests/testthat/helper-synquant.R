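# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Random valid parameter set; small n by default so brute-force
# enumeration stays cheap.
rand_params <- function(n_max = 4,
                        variant = c("depression_facilitation",
                                    "depression_only",
                                    "facilitation_doubling")) {
  variant <- sample(match.arg(variant, several.ok = TRUE), 1)
  p0 <- switch(variant,
               facilitation_doubling = runif(1, 0.1, 0.45),
               runif(1, 0.1, 0.8))
  p1 <- switch(variant,
               depression_facilitation = runif(1, p0 + 0.05, 0.95),
               NULL)
  mu_a <- runif(1, 0.1, 0.5)
  model_params(n = sample.int(n_max, 1), tau_D = runif(1, 0.05, 1),
               tau_F = runif(1, 0.05, 1), p0 = p0, p1 = p1,
               mu_a = mu_a, sigma_a = runif(1, 0.03, 0.8 * mu_a),
               sigma_b = runif(1, 0.02, 0.1), variant = variant)
}

# Random spike train: regular or Poisson, rates in the 10-50 Hz range.
rand_spikes <- function(M_max = 5, M = sample.int(M_max, 1)) {
  rate <- runif(1, 10, 50)
  if (runif(1) < 0.5) regular_train(rate, M) else poisson_train(rate, M)
}

rand_sweep <- function(params, spikes) {
  simulate_sweep(params, spikes)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
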