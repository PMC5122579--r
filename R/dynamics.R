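#' Deterministic release and restock schedules
#'
#' Given model parameters and a spike train, the short-term-plasticity
#' state is deterministic: the per-spike release probability `u_m` (just
#' before spike m), its facilitated value `u_m+` (just after), and the
#' per-interval restock probability `g_m` can all be computed in closed
#' form from event-driven exponential decay -- no time discretisation.
#'
#' The release probability starts at `u_1 = p0`, jumps at each spike by
#' `(1 - u)(p1 - p0)/(1 - p0)` (which caps it below 1), and relaxes back
#' towards `p0` between spikes with timescale `tau_F`:
#' \deqn{u_m^+ = u_m + (1 - u_m)\frac{p_1 - p_0}{1 - p_0}, \qquad
#'       u_{m+1} = p_0 + (u_m^+ - p_0) e^{-T_m/\tau_F}.}
#' An empty site restocks within an interval of length `T_m` with
#' probability \eqn{g_m = 1 - e^{-T_m/\tau_D}} (Poissonian restock).
#'
#' @param params a [model_params()] object.
#' @param spikes a spike train ([spike_train()] or numeric vector of
#'   strictly increasing times in seconds).
#' @return `release_schedule()`: a list with components `u_pre` (length M),
#'   `u_post` (length M) and `g` (length M - 1).
#' @examples
#' p <- reference_params()
#' release_schedule(p, regular_train(30, 5))
#' @export
release_schedule <- function(params, spikes) {
  validate_params(params)
  times <- as.numeric(spike_train(spikes))
  M <- length(times)
  Tm <- diff(times)
  jump <- (params$p1 - params$p0) / (1 - params$p0)
  u_pre <- numeric(M)
  u_post <- numeric(M)
  u_pre[1] <- params$p0
  for (m in seq_len(M)) {
    u_post[m] <- u_pre[m] + (1 - u_pre[m]) * jump
    if (m < M) {
      u_pre[m + 1] <- params$p0 + (u_post[m] - params$p0) * exp(-Tm[m] / params$tau_F)
    }
  }
  g <- if (M > 1) 1 - exp(-Tm / params$tau_D) else numeric(0)
  list(u_pre = u_pre, u_post = u_post, g = g)
}

#' @rdname release_schedule
#' @return `release_probabilities()`: the `u_pre`/`u_post` components only.
#' @export
release_probabilities <- function(params, spikes) {
  release_schedule(params, spikes)[c("u_pre", "u_post")]
}

#' @rdname release_schedule
#' @return `restock_probabilities()`: the vector `g` of length M - 1
#'   (empty for a single spike).
#' @export
restock_probabilities <- function(params, spikes) {
  release_schedule(params, spikes)$g
}

#' Analytic mean site occupancy before and after each spike
#'
#' Propagates the expected single-site occupancy through the train:
#' \eqn{\langle x\rangle_m^+ = \langle x\rangle_m^-(1 - u_m)} and
#' \eqn{\langle x\rangle_{m+1}^- = 1 - (1 - \langle x\rangle_m^+)(1 - g_m)},
#' starting from the fully stocked state \eqn{\langle x\rangle_1^- = 1}.
#' Because sites are statistically independent, the occupancy count just
#' before spike m is exactly Binomial(n, `before[m]`).
#'
#' @inheritParams release_schedule
#' @return A list with numeric vectors `before` and `after`, both of
#'   length M, values in \[0, 1\].
#' @export
mean_occupancy <- function(params, spikes) {
  sched <- release_schedule(params, spikes)
  M <- length(sched$u_pre)
  before <- numeric(M)
  after <- numeric(M)
  before[1] <- 1
  for (m in seq_len(M)) {
    after[m] <- before[m] * (1 - sched$u_pre[m])
    if (m < M) before[m + 1] <- 1 - (1 - after[m]) * (1 - sched$g[m])
  }
  list(before = before, after = after)
}

#' Expected EPSP amplitude at each spike
#'
#' The mean number of released vesicles at spike m is
#' \eqn{n \langle x\rangle_m^- u_m}; each contributes `mu_a` mV on
#' average and the background noise has zero mean, so the expected
#' amplitude is their product. Useful for mean-response curves and as a
#' Monte-Carlo cross-check of the simulator.
#'
#' @inheritParams release_schedule
#' @return numeric vector of length M, strictly positive (mV).
#' @export
expected_amplitudes <- function(params, spikes) {
  sched <- release_schedule(params, spikes)
  occ <- mean_occupancy(params, spikes)
  params$n * occ$before * sched$u_pre * params$mu_a
}
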