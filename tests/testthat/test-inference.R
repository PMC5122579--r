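# A deliberately tiny inference problem shared by several tests: one
# short sweep from a small synapse, with only n and p0 free, everything
# else clamped at the truth.
tiny_problem <- function(seed = 301, sweeps = 1) {
  truth <- model_params(3, 0.25, 0.2, 0.6, 0.8, 0.25, 0.1, 0.05)
  ds <- simulate_dataset(truth, protocol_regular(sweeps, 30, 5), seed = seed)
  grid <- parameter_grid(n = 1:6, p0 = seq(0.2, 0.9, by = 0.1),
                         tau_D = 0.25, tau_F = 0.2, p1 = 0.8,
                         mu_a = 0.25, sigma_a = 0.1, sigma_b = 0.05)
  list(truth = truth, ds = ds, grid = grid)
}

test_that("grid construction flags free and clamped parameters", {
  g <- parameter_grid()
  expect_true(all(g$free))
  expect_equal(length(g$values$n), 50)
  g2 <- parameter_grid(n = 1:10, tau_D = 0.25)
  expect_false(g2$free["tau_D"])
  expect_true(g2$free["n"])
  gd <- parameter_grid(variant = "depression_only")
  expect_false(gd$free["p1"])
  expect_false(gd$free["tau_F"])  # inert under depression-only dynamics
  expect_error(parameter_grid(p0 = c(0.5, 0.3)), "increasing")
  expect_error(parameter_grid(n = c(1.5, 2.5)), "integer")
})

test_that("fixed seed gives a bit-identical chain; start point is honoured", {
  tp <- tiny_problem()
  c1 <- metropolis_hastings(tp$ds, tp$grid, "correlated", 2000, 100, seed = 4)
  c2 <- metropolis_hastings(tp$ds, tp$grid, "correlated", 2000, 100, seed = 4)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$loglik, c2$loglik)
  c3 <- metropolis_hastings(tp$ds, tp$grid, "correlated", 50, 0, seed = 4,
                            start = list(n = 6, p0 = 0.7))
  expect_equal(unname(c3$samples[1, "n"]) <= 6, TRUE)
  expect_error(metropolis_hastings(tp$ds, tp$grid, "correlated", 100, 200,
                                   seed = 1))
})

test_that("single free point gives a constant chain; flat directions mix uniformly", {
  tp <- tiny_problem()
  g1 <- parameter_grid(n = c(2, 3), p0 = 0.6, tau_D = 0.25, tau_F = 0.2,
                       p1 = 0.8, mu_a = 0.25, sigma_a = 0.1, sigma_b = 0.05)
  # two-point grid: long-run occupancy ratio equals the likelihood ratio
  post <- exhaustive_posterior(tp$ds, g1, "correlated")
  ch <- metropolis_hastings(tp$ds, g1, "correlated", 4e4, 2e3, seed = 9)
  h <- marginal_posterior(ch, "n")
  r_exact <- post$prob[post$n == 3] / post$prob[post$n == 2]
  r_mcmc <- h$prob[h$value == 3] / h$prob[h$value == 2]
  expect_lt(abs(log(r_mcmc) - log(r_exact)), 0.15)
  # likelihood-flat direction (tau_F grid under depression-only dynamics):
  # uniform stationary law on a 3-point chain
  truth_d <- model_params(3, 0.25, 0.2, 0.6, mu_a = 0.25, sigma_a = 0.1,
                          sigma_b = 0.05, variant = "depression_only")
  dsd <- simulate_dataset(truth_d, protocol_regular(1, 30, 5), seed = 5)
  gflat <- parameter_grid(n = 3, p0 = 0.6, tau_D = 0.25,
                          tau_F = c(0.1, 0.2, 0.4), mu_a = 0.25,
                          sigma_a = 0.1, sigma_b = 0.05,
                          variant = "depression_only")
  chf <- metropolis_hastings(dsd, gflat, "correlated", 3e4, 1e3, seed = 10)
  hf <- marginal_posterior(chf, "tau_F")
  # ends propose off-grid half the time: stationary acceptance is 2/3
  expect_lt(abs(chf$acceptance_rate - 2 / 3), 0.05)
  expect_true(all(abs(hf$prob - 1 / 3) < 0.02))
})

test_that("MH occupancy matches the exhaustive grid posterior", {
  tp <- tiny_problem()
  post <- exhaustive_posterior(tp$ds, tp$grid, "correlated")
  ch <- metropolis_hastings(tp$ds, tp$grid, "correlated", 1e5, 1e4, seed = 6)
  for (p in c("n", "p0")) {
    h <- marginal_posterior(ch, p)
    exact <- vapply(h$value, function(v)
      sum(post$prob[abs(post[[p]] - v) < 1e-12]), numeric(1))
    expect_lt(0.5 * sum(abs(h$prob - exact)), 0.05)
  }
  # MAP from the chain agrees with the exhaustive argmax
  best <- post[which.max(post$loglik), ]
  mp <- map_estimate(ch)
  expect_equal(unname(mp["n"]), best$n)
  expect_equal(unname(mp["p0"]), best$p0)
})

test_that("marginal and pairwise histograms are consistent", {
  tp <- tiny_problem()
  ch <- metropolis_hastings(tp$ds, tp$grid, "correlated", 5000, 500, seed = 2)
  h <- marginal_posterior(ch, "n")
  expect_equal(sum(h$prob), 1)
  tab <- pairwise_posterior(ch, "n", "p0")
  expect_equal(sum(tab), 1)
  expect_equal(unname(rowSums(tab)), h$prob)
  expect_equal(unname(colSums(tab)), marginal_posterior(ch, "p0")$prob)
  expect_error(marginal_posterior(ch, "banana"), "unknown parameter")
})

test_that("credible intervals count tails outward on the histogram", {
  # uniform histogram on 100 points at level 0.95 spans ~95 points
  ci <- synquant:::credible_interval_hist(1:100, rep(0.01, 100), 0.95)
  expect_equal(unname(ci), c(3, 98))
  # degenerate: all mass on one grid point
  ci0 <- synquant:::credible_interval_hist(1:5, c(0, 0, 1, 0, 0), 0.95)
  expect_equal(unname(ci0), c(3, 3))
  # interval width shrinks (statistically) with more data
  w <- vapply(c(1, 6), function(ns) {
    tp <- tiny_problem(seed = 55, sweeps = ns)
    ch <- metropolis_hastings(tp$ds, tp$grid, "correlated", 2e4, 2e3,
                              seed = 3)
    ci <- credible_interval(ch, "n")
    ci["hi"] - ci["lo"]
  }, numeric(1))
  expect_lte(w[2], w[1])
})

test_that("convergence check separates mixed from unmixed chains", {
  tp <- tiny_problem()
  corners <- list(list(n = 1, p0 = 0.2), list(n = 6, p0 = 0.7))
  long <- lapply(seq_along(corners), function(i)
    metropolis_hastings(tp$ds, tp$grid, "correlated", 4e4, 4e3,
                        seed = 20 + i, start = corners[[i]]))
  rep_long <- convergence_check(long)
  expect_true(rep_long$pass)
  expect_true(all(rep_long$tv < 0.1))
  short <- lapply(seq_along(corners), function(i)
    metropolis_hastings(tp$ds, tp$grid, "correlated", 60, 0,
                        seed = 30 + i, start = corners[[i]]))
  expect_false(convergence_check(short)$pass)
  expect_error(convergence_check(long[1]), "two chains")
  # identical chains have distance exactly zero
  same <- convergence_check(list(long[[1]], long[[1]]))
  expect_equal(unname(same$tv), rep(0, 2))
})

test_that("posterior summary collects MAP, intervals and acceptance", {
  tp <- tiny_problem()
  ch <- metropolis_hastings(tp$ds, tp$grid, "correlated", 5000, 500, seed = 2)
  s <- posterior_summary(ch)
  expect_s3_class(s, "synq_summary")
  expect_named(s$credible_intervals, c("n", "p0"))
  expect_true(s$map$loglik >= max(ch$loglik) - 1e-12)
  expect_equal(s$level, 0.95)
  mm <- map_estimate(ch, "marginal")
  expect_true(all(c("n", "p0") %in% names(mm)))
})
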