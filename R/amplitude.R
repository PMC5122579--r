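#' Quantal amplitude distribution given k released vesicles
#'
#' A single released vesicle contributes a gamma-distributed amplitude
#' with mean `mu_a` and standard deviation `sigma_a`. The sum of `k`
#' i.i.d. gamma quanta is again gamma with shape
#' \eqn{\beta = k \mu_a^2/\sigma_a^2} and rate
#' \eqn{\lambda = \mu_a/\sigma_a^2}; `k = 0` is the degenerate point mass
#' at zero (reported with `beta = 0`).
#'
#' @param k non-negative integer release count.
#' @param params a [model_params()] object.
#' @return A list with `beta` (shape), `lam` (rate, 1/mV) and `k`.
#' @examples
#' quantal_shape(1, reference_params())  # beta = 6.25, lam = 25
#' @export
quantal_shape <- function(k, params) {
  validate_params(params)
  k <- as.integer(k)
  if (any(k < 0)) stop("'k' must be a non-negative integer")
  list(beta = k * params$mu_a^2 / params$sigma_a^2,
       lam = params$mu_a / params$sigma_a^2,
       k = k)
}

#' Log-density of an observed amplitude given k released vesicles
#'
#' The observed amplitude is `A = psi + phi` where `psi` is the
#' gamma-distributed sum of `k` quanta (zero for `k = 0`) and `phi` is
#' independent Gaussian background noise with s.d. `sigma_b`. For
#' `k >= 1` the density is the gamma-Gaussian convolution
#' \deqn{P[A|k] = \frac{\lambda^\beta}{\Gamma(\beta)\sqrt{2\pi\sigma_b^2}}
#'   \int_0^\infty \! dy\, e^{-\lambda y} y^{\beta-1}
#'   e^{-(A-y)^2/2\sigma_b^2},}
#' evaluated by fixed-order Gauss-Legendre quadrature in log space on a
#' window around the integrand's mode (the model invariant
#' `mu_a > sigma_a` makes `beta > 1`, so the integrand is strictly
#' log-concave with no endpoint singularity). For `k = 0` the Gaussian
#' log-density is returned analytically. Negative amplitudes are legal
#' (noise-dominated events); the density is strictly positive on the
#' whole real line.
#'
#' @param A numeric vector of observed amplitudes (mV); must be finite.
#' @param k a single non-negative integer release count.
#' @inheritParams quantal_shape
#' @return numeric vector of log-densities (natural scale is 1/mV).
#' @examples
#' exp(amplitude_log_density(0, 0, reference_params()))  # ~7.9788 = dnorm(0, 0, 0.05)
#' @export
amplitude_log_density <- function(A, k, params) {
  validate_params(params)
  if (length(k) != 1L || k < 0 || k != as.integer(k))
    stop("'k' must be a single non-negative integer")
  if (any(!is.finite(A))) stop("amplitudes must be finite")
  .amp_log_density_cpp(as.numeric(A), as.integer(k),
                       params$mu_a, params$sigma_a, params$sigma_b)
}

#' Slow adaptive-quadrature reference for the amplitude density
#'
#' Evaluates the same gamma-Gaussian convolution with
#' [stats::integrate()] (adaptive quadrature on the natural scale).
#' Used as an independent numerical check of the fast Gauss-Legendre
#' path; not suitable for inner inference loops.
#'
#' @inheritParams amplitude_log_density
#' @return numeric vector of densities (natural scale).
#' @export
amplitude_density_reference <- function(A, k, params) {
  validate_params(params)
  if (k == 0) return(stats::dnorm(A, 0, params$sigma_b))
  qs <- quantal_shape(k, params)
  vapply(A, function(a) {
    f <- function(y) stats::dgamma(y, shape = qs$beta, rate = qs$lam) *
      stats::dnorm(a - y, 0, params$sigma_b)
    stats::integrate(f, lower = 0, upper = Inf,
                     rel.tol = 1e-10, abs.tol = 0)$value
  }, numeric(1))
}

#' Precomputed table of amplitude densities
#'
#' Computes `P[A_i | k]` on the natural scale for every amplitude and
#' every release count `k = 0..k_max` (normally `k_max = n`). This is the
#' building block shared by all the likelihood matrices of one
#' evaluation.
#'
#' @param amps numeric vector of amplitudes (mV).
#' @param k_max maximum release count (typically `params$n`).
#' @inheritParams quantal_shape
#' @return numeric matrix `length(amps)` x `(k_max + 1)`; column `k + 1`
#'   holds `P[A | k]`. All entries finite and strictly positive.
#' @export
amplitude_density_table <- function(amps, k_max, params) {
  validate_params(params)
  stopifnot(k_max >= 0, all(is.finite(amps)))
  tab <- .amp_density_table_cpp(as.numeric(amps), as.integer(k_max),
                                params$mu_a, params$sigma_a, params$sigma_b)
  dimnames(tab) <- list(NULL, paste0("k", 0:k_max))
  tab
}
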