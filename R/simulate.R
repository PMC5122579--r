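#' Stimulation protocols
#'
#' A protocol describes how synthetic sweeps are generated: how many
#' sweeps, and the spike pattern within each sweep. Sweeps are separated
#' by enough time for full vesicle-pool recovery, so every sweep starts
#' from the fully stocked state and sweeps are statistically independent.
#'
#' @param sweep_count number of sweeps (>= 1).
#' @param rate_hz stimulation rate in Hz.
#' @param n_spikes spikes per sweep.
#' @return an object of class `"synq_protocol"`.
#' @export
protocol_regular <- function(sweep_count, rate_hz, n_spikes) {
  stopifnot(sweep_count >= 1, rate_hz > 0, n_spikes >= 1)
  structure(list(sweep_count = as.integer(sweep_count), pattern = "regular",
                 rate_hz = rate_hz, n_spikes = as.integer(n_spikes)),
            class = "synq_protocol")
}

#' @rdname protocol_regular
#' @export
protocol_poisson <- function(sweep_count, rate_hz, n_spikes) {
  stopifnot(sweep_count >= 1, rate_hz > 0, n_spikes >= 1)
  structure(list(sweep_count = as.integer(sweep_count), pattern = "poisson",
                 rate_hz = rate_hz, n_spikes = as.integer(n_spikes)),
            class = "synq_protocol")
}

#' @rdname protocol_regular
#' @param times explicit spike times used for every sweep.
#' @export
protocol_explicit <- function(sweep_count, times) {
  stopifnot(sweep_count >= 1)
  structure(list(sweep_count = as.integer(sweep_count), pattern = "explicit",
                 times = as.numeric(spike_train(times))),
            class = "synq_protocol")
}

#' Simulate one sweep of the stochastic synapse
#'
#' Simulates the `n` release sites independently: every site starts
#' stocked; at spike `m` an occupied site releases with probability `u_m`
#' (from the deterministic schedule); a site left empty refills before
#' the next spike with probability `g_m` -- an exact Bernoulli draw for
#' the Poissonian restock model, with no time discretisation. The
#' amplitude at spike `m` is a single gamma draw with shape
#' `k_m * mu_a^2 / sigma_a^2` and rate `mu_a / sigma_a^2` (exact for the
#' sum of `k_m` i.i.d. quanta) plus Gaussian background noise; `k_m = 0`
#' gives a pure noise draw. Uses the current RNG state.
#'
#' @param params a [model_params()] object.
#' @param spikes spike train (times in seconds).
#' @param return_truth if `TRUE`, attach the latent release counts `k`
#'   and pre-spike occupancies `y_before` as attributes.
#' @return a [sweep_data()] object; with `return_truth = TRUE` it carries
#'   attributes `k` and `y_before` (integer vectors, diagnostics only --
#'   never consumed by inference).
#' @export
simulate_sweep <- function(params, spikes, return_truth = FALSE) {
  validate_params(params)
  times <- as.numeric(spike_train(spikes))
  sched <- release_schedule(params, times)
  M <- length(times)
  n <- params$n
  occupied <- rep(TRUE, n)
  k <- integer(M)
  y_before <- integer(M)
  for (m in seq_len(M)) {
    y_before[m] <- sum(occupied)
    release <- occupied & (stats::runif(n) < sched$u_pre[m])
    k[m] <- sum(release)
    occupied <- occupied & !release
    if (m < M) {
      refill <- !occupied & (stats::runif(n) < sched$g[m])
      occupied <- occupied | refill
    }
  }
  qs <- quantal_shape(1L, params)
  psi <- ifelse(k > 0,
                stats::rgamma(M, shape = k * qs$beta, rate = qs$lam), 0)
  amps <- psi + stats::rnorm(M, 0, params$sigma_b)
  sw <- sweep_data(times, amps)
  if (return_truth) {
    attr(sw, "k") <- k
    attr(sw, "y_before") <- y_before
  }
  sw
}

#' Simulate a dataset of independent sweeps
#'
#' Draws `sweep_count` independent sweeps under a [protocol][protocol_regular].
#' The root `seed` spawns one child seed per sweep (drawn up front), so
#' sweep `i` is identical whatever the total sweep count -- convenient
#' for nested experiments that grow the dataset.
#'
#' @param params a [model_params()] object.
#' @param protocol a `"synq_protocol"` object.
#' @param seed integer root seed.
#' @param return_truth attach latent `k`/`y_before` per sweep.
#' @return a [sweep_dataset()] object.
#' @export
simulate_dataset <- function(params, protocol, seed, return_truth = FALSE) {
  stopifnot(inherits(protocol, "synq_protocol"))
  set.seed(seed)
  child <- sample.int(2147483646L, protocol$sweep_count)
  sweeps <- lapply(seq_len(protocol$sweep_count), function(i) {
    set.seed(child[i])
    times <- switch(protocol$pattern,
      regular = regular_train(protocol$rate_hz, protocol$n_spikes),
      poisson = poisson_train(protocol$rate_hz, protocol$n_spikes),
      explicit = spike_train(protocol$times))
    simulate_sweep(params, times, return_truth = return_truth)
  })
  sweep_dataset(sweeps)
}

#' Empirical release-count marginals by Monte-Carlo
#'
#' Repeatedly simulates the release process (amplitudes are irrelevant
#' here) and tabulates per-spike release-count frequencies, with
#' binomial standard errors. Serves as the Monte-Carlo oracle for
#' [joint_release_probability()].
#'
#' @param params a [model_params()] object.
#' @param spikes spike train.
#' @param n_rep number of simulated sweeps.
#' @param seed integer seed.
#' @return a list with `counts` (matrix `n_rep x M` of release counts),
#'   `marginal` (matrix `(n+1) x M` of frequencies) and `se` (matching
#'   standard errors).
#' @export
empirical_release_marginals <- function(params, spikes, n_rep, seed) {
  validate_params(params)
  stopifnot(n_rep >= 1)
  times <- as.numeric(spike_train(spikes))
  sched <- release_schedule(params, times)
  M <- length(times)
  n <- params$n
  set.seed(seed)
  counts <- matrix(0L, n_rep, M)
  # vectorised over replicates: occupancy matrix n_rep x n
  occupied <- matrix(TRUE, n_rep, n)
  for (m in seq_len(M)) {
    release <- occupied & (matrix(stats::runif(n_rep * n), n_rep, n) <
                             sched$u_pre[m])
    counts[, m] <- rowSums(release)
    occupied <- occupied & !release
    if (m < M) {
      refill <- !occupied & (matrix(stats::runif(n_rep * n), n_rep, n) <
                               sched$g[m])
      occupied <- occupied | refill
    }
  }
  marginal <- vapply(seq_len(M), function(m)
    tabulate(counts[, m] + 1L, nbins = n + 1L) / n_rep, numeric(n + 1))
  se <- sqrt(marginal * (1 - marginal) / n_rep)
  dimnames(marginal) <- dimnames(se) <-
    list(paste0("k", 0:n), paste0("spike", seq_len(M)))
  list(counts = counts, marginal = marginal, se = se)
}
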