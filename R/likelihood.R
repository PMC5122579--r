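#' Sweeps and datasets of amplitude trains
#'
#' A sweep pairs a presynaptic spike train with the postsynaptic
#' amplitudes it evoked; a dataset is a collection of statistically
#' independent sweeps (each sweep starts from a fully recovered synapse).
#'
#' @param times spike times in seconds (strictly increasing).
#' @param amplitudes observed EPSP amplitudes in mV (finite; may be
#'   negative for noise-dominated events), same length as `times`.
#' @return `sweep_data()`: an object of class `"synq_sweep"`;
#'   `sweep_dataset()`: an object of class `"synq_dataset"`.
#' @export
sweep_data <- function(times, amplitudes) {
  times <- spike_train(times)
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != length(times))
    stop("'times' and 'amplitudes' must have the same length")
  if (any(!is.finite(amplitudes))) stop("amplitudes must be finite")
  structure(list(times = as.numeric(times), amplitudes = amplitudes),
            class = "synq_sweep")
}

#' @rdname sweep_data
#' @param sweeps a list of `"synq_sweep"` objects (non-empty).
#' @export
sweep_dataset <- function(sweeps) {
  if (inherits(sweeps, "synq_sweep")) sweeps <- list(sweeps)
  if (length(sweeps) == 0) stop("a dataset must contain at least one sweep")
  if (!all(vapply(sweeps, inherits, logical(1), "synq_sweep")))
    stop("all elements must be 'synq_sweep' objects")
  structure(list(sweeps = sweeps), class = "synq_dataset")
}

as_theta <- function(params) {
  c(params$n, params$tau_D, params$tau_F, params$p0, params$p1,
    params$mu_a, params$sigma_a, params$sigma_b)
}

#' Binomial release and restock kernels
#'
#' `release_pmf()` is the probability that `k` of the `y` occupied sites
#' release, each independently with probability `u`:
#' \eqn{C(y,k) u^k (1-u)^{y-k}}. `restock_pmf()` is the probability that
#' the occupancy just before the next spike is `y_next`, given `y`
#' occupied sites of which `k` released (leaving `n - y + k` empty sites
#' that each refill independently with probability `g`).
#'
#' @param k release count, `0 <= k <= y`.
#' @param y occupancy just before the spike.
#' @param u per-site release probability in `[0, 1]`.
#' @return a probability.
#' @export
release_pmf <- function(k, y, u) {
  stopifnot(k >= 0, y >= 0, u >= 0, u <= 1)
  if (k > y) return(0)
  stats::dbinom(k, size = y, prob = u)
}

#' @rdname release_pmf
#' @param y_next occupancy just before the following spike.
#' @param g per-site restock probability in `[0, 1]`.
#' @param n total number of release sites.
#' @export
restock_pmf <- function(y_next, k, y, g, n) {
  stopifnot(k >= 0, k <= y, y <= n, y_next >= 0, y_next <= n,
            g >= 0, g <= 1)
  if (y_next < y - k) return(0)
  stats::dbinom(y_next - y + k, size = n - y + k, prob = g)
}

#' Observation-weighted transition matrix and final vector
#'
#' `observation_matrix()` builds the `(n+1) x (n+1)` kernel `Q_m` that
#' advances the occupancy state across one interior spike while weighting
#' by the observed amplitude:
#' \deqn{Q_m[y', y] = \sum_{k=0}^{y} P(y'|k,y) \, P[A_m|k] \, P(k|y).}
#' `final_observation_vector()` is the terminal row vector
#' \eqn{\langle L_M|_y = \sum_k P[A_M|k] P(k|y)}. With all observation
#' weights set to 1 the kernel is column-stochastic (pure release/restock
#' chain).
#'
#' @param A observed amplitude at this spike (mV).
#' @param u release probability at this spike.
#' @param g restock probability for the following interval.
#' @param params a [model_params()] object.
#' @param dens optional vector of observation weights `P[A|k]`,
#'   `k = 0..n` (natural scale); computed from the amplitude model when
#'   `NULL`. Pass `rep(1, n + 1)` to obtain the unweighted chain kernel.
#' @return `observation_matrix()`: matrix indexed `[y_next + 1, y + 1]`;
#'   `final_observation_vector()`: numeric vector indexed `[y + 1]`.
#' @export
observation_matrix <- function(A, u, g, params, dens = NULL) {
  n <- params$n
  if (is.null(dens)) dens <- exp(vapply(0:n, function(k)
    amplitude_log_density(A, k, params), numeric(1)))
  stopifnot(length(dens) == n + 1)
  Q <- matrix(0, n + 1, n + 1)
  for (y in 0:n) {
    for (k in 0:y) {
      w <- dens[k + 1] * release_pmf(k, y, u)
      if (w == 0) next
      for (y2 in (y - k):n) {
        Q[y2 + 1, y + 1] <- Q[y2 + 1, y + 1] + w * restock_pmf(y2, k, y, g, n)
      }
    }
  }
  Q
}

#' @rdname observation_matrix
#' @export
final_observation_vector <- function(A, u, params, dens = NULL) {
  n <- params$n
  if (is.null(dens)) dens <- exp(vapply(0:n, function(k)
    amplitude_log_density(A, k, params), numeric(1)))
  stopifnot(length(dens) == n + 1)
  vapply(0:n, function(y)
    sum(dens[seq_len(y + 1)] * stats::dbinom(0:y, y, u)), numeric(1))
}

#' Exact correlated log-likelihood of an amplitude train
#'
#' Computes \eqn{\log L(A_M, \ldots, A_1 | \theta)} exactly as a scaled
#' matrix product over the hidden occupancy `y` (a forward algorithm):
#' \eqn{L = \langle L_M| Q_{M-1} \cdots Q_1 |R_0\rangle} with
#' \eqn{|R_0\rangle = \delta_{y,n}} (fully stocked start). After each
#' matrix application the state vector is renormalised and the log of its
#' sum accumulated, so the computation is stable for trains of thousands
#' of spikes; the cost is linear in the train length.
#'
#' @param sweep a [sweep_data()] object.
#' @param params a [model_params()] object.
#' @param engine `"cpp"` (fast path, default) or `"R"` (reference
#'   implementation built from [observation_matrix()]).
#' @return the log-likelihood (a single finite number).
#' @export
loglik_correlated <- function(sweep, params, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  validate_params(params)
  stopifnot(inherits(sweep, "synq_sweep"))
  if (engine == "cpp") {
    return(.loglik_sweep_cpp(sweep$times, sweep$amplitudes,
                             as_theta(params), TRUE))
  }
  sched <- release_schedule(params, sweep$times)
  n <- params$n
  M <- length(sweep$times)
  dens <- amplitude_density_table(sweep$amplitudes, n, params)
  v <- c(rep(0, n), 1)
  logL <- 0
  if (M > 1) {
    for (m in seq_len(M - 1)) {
      Q <- observation_matrix(sweep$amplitudes[m], sched$u_pre[m],
                              sched$g[m], params, dens = dens[m, ])
      v <- as.numeric(Q %*% v)
      s <- sum(v)
      logL <- logL + log(s)
      v <- v / s
    }
  }
  lM <- final_observation_vector(sweep$amplitudes[M], sched$u_pre[M],
                                 params, dens = dens[M, ])
  logL + log(sum(lM * v))
}

#' Uncorrelated (factorised) baseline log-likelihood
#'
#' Treats the amplitudes within a sweep as independent given the spike
#' times: \eqn{\log L = \sum_m \log \sum_k P[A_m|k] P(k_m = k)}, where
#' the marginal release-count law `P(k_m)` conditions on the spike times
#' but not on previously observed amplitudes. Two equivalent routes to
#' `P(k_m)` are provided: `"propagate"` advances the full occupancy
#' distribution with the amplitude-independent kernel (default);
#' `"mean_field"` uses the closed form `Binomial(n, <x>_m u_m)`, which is
#' exact here because sites are marginally independent.
#'
#' @inheritParams loglik_correlated
#' @param marginal how to compute the marginal release-count law.
#' @return the log-likelihood.
#' @export
loglik_uncorrelated <- function(sweep, params, engine = c("cpp", "R"),
                                marginal = c("propagate", "mean_field")) {
  engine <- match.arg(engine)
  marginal <- match.arg(marginal)
  validate_params(params)
  stopifnot(inherits(sweep, "synq_sweep"))
  if (engine == "cpp" && marginal == "propagate") {
    return(.loglik_sweep_cpp(sweep$times, sweep$amplitudes,
                             as_theta(params), FALSE))
  }
  sched <- release_schedule(params, sweep$times)
  n <- params$n
  M <- length(sweep$times)
  dens <- amplitude_density_table(sweep$amplitudes, n, params)
  if (marginal == "mean_field") {
    x <- mean_occupancy(params, sweep$times)$before
    logL <- 0
    for (m in seq_len(M)) {
      pk <- stats::dbinom(0:n, n, x[m] * sched$u_pre[m])
      logL <- logL + log(sum(dens[m, ] * pk))
    }
    return(logL)
  }
  w <- c(rep(0, n), 1)
  logL <- 0
  ones <- rep(1, n + 1)
  for (m in seq_len(M)) {
    pk <- vapply(0:n, function(k)
      sum(stats::dbinom(k, 0:n, sched$u_pre[m]) * w), numeric(1))
    logL <- logL + log(sum(dens[m, ] * pk))
    if (m < M) {
      Qbar <- observation_matrix(0, sched$u_pre[m], sched$g[m], params,
                                 dens = ones)
      w <- as.numeric(Qbar %*% w)
      w <- w / sum(w)
    }
  }
  logL
}

#' Joint probability of a release-count sequence (matrix route)
#'
#' Computes \eqn{P(k_M, \ldots, k_1) = \langle l_M| q_{M-1} \cdots q_1
#' |r_0\rangle} where \eqn{\langle l|_y} is the release kernel at the
#' final spike and each \eqn{q_m} combines release of `k_m` vesicles with
#' restock over the following interval. Summed over all `(n+1)^M`
#' sequences this is exactly 1.
#'
#' @param ks integer vector of release counts, one per spike, each in
#'   `0..n`.
#' @param params a [model_params()] object.
#' @param spikes spike train.
#' @return a probability.
#' @export
joint_release_probability <- function(ks, params, spikes) {
  validate_params(params)
  times <- as.numeric(spike_train(spikes))
  M <- length(times)
  ks <- as.integer(ks)
  if (length(ks) != M) stop("'ks' must have one entry per spike")
  n <- params$n
  if (any(ks < 0 | ks > n)) stop("release counts must lie in 0..n")
  sched <- release_schedule(params, times)
  v <- c(rep(0, n), 1)
  if (M > 1) {
    for (m in seq_len(M - 1)) {
      q <- matrix(0, n + 1, n + 1)
      k <- ks[m]
      for (y in k:n) {
        w <- release_pmf(k, y, sched$u_pre[m])
        if (w == 0) next
        for (y2 in (y - k):n)
          q[y2 + 1, y + 1] <- w * restock_pmf(y2, k, y, sched$g[m], n)
      }
      v <- as.numeric(q %*% v)
    }
  }
  l <- vapply(0:n, function(y) release_pmf(ks[M], y, sched$u_pre[M]),
              numeric(1))
  sum(l * v)
}

#' Dataset log-likelihood
#'
#' Sum of per-sweep log-likelihoods; sweeps are statistically independent
#' and each restarts from the fully stocked state.
#'
#' @param dataset a [sweep_dataset()] object.
#' @param params a [model_params()] object.
#' @param mode `"correlated"` (exact matrix product) or `"uncorrelated"`
#'   (factorised baseline).
#' @return the log-likelihood.
#' @export
loglik_dataset <- function(dataset, params,
                           mode = c("correlated", "uncorrelated")) {
  mode <- match.arg(mode)
  validate_params(params)
  stopifnot(inherits(dataset, "synq_dataset"))
  .loglik_dataset_cpp(lapply(dataset$sweeps, `[[`, "times"),
                      lapply(dataset$sweeps, `[[`, "amplitudes"),
                      as_theta(params), mode == "correlated")
}

# Distribution of the per-site release sequence r in {0,1}^M for a single
# site, by direct enumeration of site histories (release and restock
# branches). Returns a vector of length 2^M indexed by
# 1 + sum(r_m 2^(m-1)). Independent of the matrix-product machinery.
site_release_distribution <- function(params, spikes) {
  sched <- release_schedule(params, spikes)
  M <- length(sched$u_pre)
  out <- numeric(2^M)
  recurse <- function(m, occupied, prob, code) {
    if (prob == 0) return(invisible())
    if (m > M) {
      out[code + 1] <<- out[code + 1] + prob
      return(invisible())
    }
    u <- sched$u_pre[m]
    g <- if (m <= length(sched$g)) sched$g[m] else NA_real_
    step <- function(after, p2, code2) {
      if (m == M) {
        recurse(m + 1, after, p2, code2)
      } else if (after == 0L) {
        recurse(m + 1, 1L, p2 * g, code2)
        recurse(m + 1, 0L, p2 * (1 - g), code2)
      } else {
        recurse(m + 1, 1L, p2, code2)
      }
    }
    if (occupied == 1L) {
      step(0L, prob * u, code + 2^(m - 1))  # release
      step(1L, prob * (1 - u), code)        # hold
    } else {
      step(0L, prob, code)
    }
  }
  recurse(1L, 1L, 1, 0L)
  out
}

# Joint pmf over release-count vectors (k_1..k_M) by convolving n
# independent per-site release-sequence distributions. Array with dim
# rep(n + 1, M); entry [k_1 + 1, ..., k_M + 1].
brute_force_joint_pmf <- function(params, spikes) {
  times <- as.numeric(spike_train(spikes))
  M <- length(times)
  n <- params$n
  site <- site_release_distribution(params, times)
  codes <- which(site > 0) - 1L
  rmat <- matrix(unlist(lapply(codes, function(cd)
    as.integer(intToBits(cd))[1:M])), ncol = M, byrow = TRUE)
  probs <- site[codes + 1L]
  dims <- rep(n + 1L, M)
  stride <- cumprod(c(1L, dims[-M]))
  dist <- numeric(prod(dims))
  dist[1] <- 1
  offsets <- as.integer(rmat %*% stride)
  for (s in seq_len(n)) {
    new <- numeric(length(dist))
    idx_nz <- which(dist > 0)
    for (j in seq_along(offsets)) {
      tgt <- idx_nz + offsets[j]
      new[tgt] <- new[tgt] + dist[idx_nz] * probs[j]
    }
    dist <- new
  }
  array(dist, dim = dims)
}

#' Brute-force likelihood by exhaustive enumeration
#'
#' Computes the train likelihood by summing
#' \eqn{\prod_m P[A_m|k_m] \, P(k_M,\ldots,k_1)} over all `(n+1)^M`
#' release sequences. The joint release probabilities are obtained by
#' direct enumeration of per-site histories (release/restock branches)
#' convolved over the `n` independent sites -- entirely independent of
#' the matrix-product code path, which makes this the exactness oracle
#' for [loglik_correlated()]. Cost grows as `(n+1)^M`; guarded at
#' `1e6` terms.
#'
#' @inheritParams loglik_correlated
#' @return the log-likelihood.
#' @export
brute_force_loglik <- function(sweep, params) {
  validate_params(params)
  stopifnot(inherits(sweep, "synq_sweep"))
  n <- params$n
  M <- length(sweep$times)
  if ((n + 1)^M > 1e6) stop("(n+1)^M exceeds the brute-force guard of 1e6")
  pmf <- brute_force_joint_pmf(params, sweep$times)
  dens <- amplitude_density_table(sweep$amplitudes, n, params)
  kgrid <- as.matrix(expand.grid(rep(list(0:n), M)))
  weights <- vapply(seq_len(nrow(kgrid)), function(i)
    prod(dens[cbind(seq_len(M), kgrid[i, ] + 1L)]), numeric(1))
  log(sum(weights * as.numeric(pmf)))
}
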