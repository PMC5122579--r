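#' Spike trains
#'
#' A spike train is a strictly increasing numeric vector of presynaptic
#' action-potential times in seconds. `spike_train()` validates an
#' explicit vector; `regular_train()` builds a periodic train and
#' `poisson_train()` draws a homogeneous-Poisson train (i.i.d. exponential
#' interspike intervals) using the current RNG state.
#'
#' @param times numeric vector of spike times (seconds), strictly
#'   increasing, all finite, length >= 1.
#' @return A numeric vector of class `"synq_spikes"`.
#' @examples
#' regular_train(rate_hz = 30, n_spikes = 5)
#' @export
spike_train <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("spike train must contain at least one spike")
  if (any(!is.finite(times))) stop("spike times must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  structure(times, class = "synq_spikes")
}

#' @rdname spike_train
#' @param rate_hz stimulation rate in Hz (> 0).
#' @param n_spikes number of spikes (>= 1).
#' @param t0 time of the first spike in seconds.
#' @export
regular_train <- function(rate_hz, n_spikes, t0 = 0) {
  stopifnot(rate_hz > 0, n_spikes >= 1)
  spike_train(t0 + (seq_len(n_spikes) - 1) / rate_hz)
}

#' @rdname spike_train
#' @export
poisson_train <- function(rate_hz, n_spikes, t0 = 0) {
  stopifnot(rate_hz > 0, n_spikes >= 1)
  spike_train(t0 + cumsum(c(0, stats::rexp(n_spikes - 1, rate = rate_hz))))
}

#' Interspike intervals T_m = t_{m+1} - t_m
#' @param spikes a spike train (or plain numeric vector of times).
#' @return numeric vector of length `length(spikes) - 1`.
#' @export
interspike_intervals <- function(spikes) {
  diff(as.numeric(spikes))
}
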