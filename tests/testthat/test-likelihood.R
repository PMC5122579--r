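test_that("release and restock kernels match hand-derived values", {
  expect_equal(release_pmf(0, 0, 0.7), 1)
  expect_equal(release_pmf(1, 0, 0.7), 0)
  expect_equal(release_pmf(2, 2, 1), 1)
  expect_equal(release_pmf(1, 2, 0.5), 0.5)  # 2 * 0.5 * 0.5
  expect_equal(restock_pmf(1, 1, 2, 0, n = 2), 1)   # g = 0: y' = y - k
  expect_equal(restock_pmf(2, 1, 2, 0, n = 2), 0)
  expect_equal(restock_pmf(2, 1, 1, 1, n = 2), 1)   # g = 1: all refill
  expect_equal(restock_pmf(1, 1, 1, 0.5, n = 2), 0.5)  # C(2,1) 0.5 0.5
  expect_equal(restock_pmf(0, 0, 1, 0.3, n = 2), 0)  # y' < y - k impossible
})

test_that("observation matrix reduces to the column-stochastic chain kernel", {
  set.seed(11)
  p <- rand_params(n_max = 5)
  n <- p$n
  Q <- observation_matrix(0, 0.4, 0.3, p, dens = rep(1, n + 1))
  expect_equal(colSums(Q), rep(1, n + 1))
  # n = 1 entries by hand: y=0 column stays/refills; y=1 releases or not
  p1 <- model_params(1, 0.25, 0.2, 0.6, 0.8, 0.25, 0.1, 0.05)
  u <- 0.6; g <- 0.3; dens <- c(2, 5)
  Q1 <- observation_matrix(NA_real_, u, g, p1, dens = dens)
  expect_equal(Q1[, 1], dens[1] * c(1 - g, g))
  expect_equal(Q1[, 2],
               dens[2] * u * c(1 - g, g) + dens[1] * (1 - u) * c(0, 1))
  L1 <- final_observation_vector(NA_real_, u, p1, dens = dens)
  expect_equal(L1, c(dens[1], (1 - u) * dens[1] + u * dens[2]))
  expect_equal(final_observation_vector(NA_real_, 0, p1, dens = dens),
               rep(dens[1], 2))
  expect_equal(final_observation_vector(NA_real_, 0.7, p1,
                                        dens = c(1, 1)), c(1, 1))
})

test_that("single-spike likelihood equals the closed-form mixture", {
  p1 <- model_params(1, 0.25, 0.2, 0.6, 0.8, 0.25, 0.1, 0.05)
  sw <- sweep_data(0, 0.21)
  d0 <- exp(amplitude_log_density(0.21, 0, p1))
  d1 <- exp(amplitude_log_density(0.21, 1, p1))
  expect_equal(loglik_correlated(sw, p1), log(0.4 * d0 + 0.6 * d1))
  expect_equal(loglik_uncorrelated(sw, p1), loglik_correlated(sw, p1))
  expect_equal(brute_force_loglik(sw, p1), loglik_correlated(sw, p1))
})

test_that("matrix-product likelihood equals the enumeration oracle", {
  set.seed(20)
  for (rep in 1:25) {
    p <- rand_params(n_max = 4)
    spikes <- rand_spikes(M_max = 5)
    sw <- simulate_sweep(p, spikes)
    bf <- brute_force_loglik(sw, p)
    expect_rel_equal(loglik_correlated(sw, p), bf, 1e-10)
    expect_rel_equal(loglik_correlated(sw, p, engine = "R"), bf, 1e-10)
  }
})

test_that("joint release probability: hand cases and normalisation", {
  p1 <- model_params(1, 0.25, 0.2, 0.6, 0.8, 0.25, 0.1, 0.05)
  spikes <- regular_train(30, 2)
  sch <- release_schedule(p1, spikes)
  expect_equal(joint_release_probability(c(1, 1), p1, spikes),
               sch$u_pre[1] * sch$g[1] * sch$u_pre[2])
  pg0 <- model_params(1, 1e12, 0.2, 0.6, 0.8, 0.25, 0.1, 0.05)
  expect_lt(joint_release_probability(c(1, 1), pg0, spikes), 1e-10)
  set.seed(21)
  for (rep in 1:5) {
    p <- rand_params(n_max = 3)
    spikes <- rand_spikes(M = 4)
    ks <- as.matrix(expand.grid(rep(list(0:p$n), 4)))
    tot <- sum(apply(ks, 1, joint_release_probability, params = p,
                     spikes = spikes))
    expect_lt(abs(tot - 1), 1e-12)
    expect_equal(nrow(ks), (p$n + 1)^4)
    # cross-check the matrix route against direct site-history enumeration
    pmf <- synquant:::brute_force_joint_pmf(p, spikes)
    for (i in sample(nrow(ks), 10))
      expect_rel_equal(joint_release_probability(ks[i, ], p, spikes) + 1e-30,
                       pmf[matrix(ks[i, ] + 1L, 1)] + 1e-30, 1e-10)
  }
})

test_that("full restock (g -> 1) collapses correlated onto uncorrelated", {
  set.seed(22)
  for (rep in 1:5) {
    p <- rand_params(n_max = 4)
    p_fast <- model_params(p$n, 1e-4, p$tau_F, p$p0,
                           if (p$variant == "depression_facilitation") p$p1,
                           p$mu_a, p$sigma_a, p$sigma_b, variant = p$variant)
    sw <- simulate_sweep(p_fast, regular_train(30, 10))
    expect_lt(abs(loglik_correlated(sw, p_fast) -
                    loglik_uncorrelated(sw, p_fast)), 1e-8)
  }
})

test_that("uncorrelated marginals: propagation equals the binomial closed form", {
  set.seed(23)
  for (rep in 1:8) {
    p <- rand_params(n_max = 5)
    sw <- simulate_sweep(p, rand_spikes(M = 6))
    u_prop <- loglik_uncorrelated(sw, p, engine = "R", marginal = "propagate")
    u_mf <- loglik_uncorrelated(sw, p, engine = "R", marginal = "mean_field")
    u_cpp <- loglik_uncorrelated(sw, p, engine = "cpp")
    expect_rel_equal(u_prop, u_mf, 1e-10)
    expect_rel_equal(u_cpp, u_prop, 1e-10)
  }
})

test_that("correlated and uncorrelated differ for a strongly depressing synapse", {
  p <- model_params(2, 10, 0.2, 0.9, mu_a = 0.25, sigma_a = 0.1,
                    sigma_b = 0.05, variant = "depression_only")
  set.seed(24)
  sw <- simulate_sweep(p, regular_train(30, 3))
  expect_gt(abs(loglik_correlated(sw, p) - loglik_uncorrelated(sw, p)),
            1e-3)
})

test_that("dataset log-likelihood is additive and exchangeable", {
  set.seed(25)
  p <- rand_params(n_max = 4)
  sw1 <- simulate_sweep(p, regular_train(30, 5))
  sw2 <- simulate_sweep(p, regular_train(40, 4))
  for (mode in c("correlated", "uncorrelated")) {
    l1 <- loglik_dataset(sweep_dataset(list(sw1)), p, mode)
    l12 <- loglik_dataset(sweep_dataset(list(sw1, sw2)), p, mode)
    l21 <- loglik_dataset(sweep_dataset(list(sw2, sw1)), p, mode)
    l11 <- loglik_dataset(sweep_dataset(list(sw1, sw1)), p, mode)
    expect_equal(l12, l21)
    expect_equal(l11, 2 * l1)
    expect_equal(l12 - l1,
                 loglik_dataset(sweep_dataset(list(sw2)), p, mode))
  }
})

test_that("M = 1 likelihood normalises over the amplitude", {
  p <- model_params(3, 0.25, 0.2, 0.6, 0.8, 0.25, 0.1, 0.05)
  A <- seq(-0.6, 2.2, length.out = 3001)
  f <- vapply(A, function(a)
    exp(loglik_correlated(sweep_data(0, a), p)), numeric(1))
  expect_lt(abs(sum(f) * (A[2] - A[1]) - 1), 1e-5)
})

test_that("scaled forward pass stays finite and linear for long trains", {
  p <- reference_params()
  set.seed(26)
  sw_long <- simulate_sweep(p, regular_train(30, 1000))
  t1 <- system.time(l <- loglik_correlated(sw_long, p))["elapsed"]
  expect_true(is.finite(l))
  expect_lt(t1, 5)  # 1000 spikes must be effectively instantaneous
  # probability conservation through the scaled arithmetic: unit
  # observation weights make the matrix product exactly 1
  n <- 3
  p3 <- model_params(n, 0.25, 0.2, 0.6, 0.8, 0.25, 0.1, 0.05)
  sch <- release_schedule(p3, regular_train(30, 50))
  v <- c(rep(0, n), 1); logs <- 0
  for (m in 1:49) {
    Q <- observation_matrix(0, sch$u_pre[m], sch$g[m], p3,
                            dens = rep(1, n + 1))
    v <- as.numeric(Q %*% v); s <- sum(v); logs <- logs + log(s); v <- v / s
  }
  tot <- exp(logs) * sum(final_observation_vector(0, sch$u_pre[50], p3,
                                                  dens = rep(1, n + 1)) * v)
  expect_lt(abs(tot - 1), 1e-12)
})

test_that("brute force respects its size guard", {
  p <- model_params(9, 0.25, 0.2, 0.6, 0.8, 0.25, 0.1, 0.05)
  sw <- sweep_data(regular_train(30, 7), rep(0.2, 7))  # 10^7 terms
  expect_error(brute_force_loglik(sw, p), "guard")
})
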