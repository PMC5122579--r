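#' Synaptic model parameters
#'
#' Construct and validate the parameter set of the stochastic quantal
#' synapse model: `n` independent release sites, Poissonian restock with
#' timescale `tau_D`, spike-triggered facilitation of the release
#' probability decaying with timescale `tau_F`, gamma-distributed quantal
#' amplitudes and additive Gaussian background noise.
#'
#' Three model variants are supported:
#' \describe{
#'   \item{`"depression_facilitation"`}{full model; requires `p0 < p1`.}
#'   \item{`"depression_only"`}{no facilitation; `p1` is tied to `p0`
#'     (any supplied `p1` must equal `p0` or be missing).}
#'   \item{`"facilitation_doubling"`}{reduced facilitation model where the
#'     release probability doubles after an isolated spike; `p1 = 2 * p0`
#'     is enforced at construction and `p1` is not a free parameter.}
#' }
#'
#' @param n integer, number of release sites (>= 1).
#' @param tau_D depression (restock) timescale in seconds, > 0.
#' @param tau_F facilitation decay timescale in seconds, > 0.
#' @param p0 baseline release probability, in (0, 1).
#' @param p1 facilitated release probability immediately after an isolated
#'   spike. Ignored (derived) for `"depression_only"` and
#'   `"facilitation_doubling"`.
#' @param mu_a mean quantal amplitude in mV; must exceed `sigma_a` so that
#'   zero is not the most likely single-vesicle amplitude.
#' @param sigma_a standard deviation of the quantal amplitude in mV, > 0.
#' @param sigma_b standard deviation of the Gaussian background noise in
#'   mV, > 0.
#' @param variant model variant, see Details.
#'
#' @return An object of class `"synq_params"`: a named list of the eight
#'   parameters plus the variant tag.
#' @examples
#' model_params(n = 7, tau_D = 0.25, tau_F = 0.2, p0 = 0.6, p1 = 0.8,
#'              mu_a = 0.25, sigma_a = 0.1, sigma_b = 0.05)
#' @export
model_params <- function(n, tau_D, tau_F, p0, p1 = NULL,
                         mu_a, sigma_a, sigma_b,
                         variant = c("depression_facilitation",
                                     "depression_only",
                                     "facilitation_doubling")) {
  variant <- match.arg(variant)
  if (variant == "depression_only") {
    if (!is.null(p1) && !isTRUE(all.equal(p1, p0))) {
      stop("'p1' must equal 'p0' (or be omitted) for variant 'depression_only'")
    }
    p1 <- p0
  } else if (variant == "facilitation_doubling") {
    if (!is.null(p1) && !isTRUE(all.equal(p1, 2 * p0))) {
      stop("'p1' must equal 2 * 'p0' (or be omitted) for variant 'facilitation_doubling'")
    }
    p1 <- 2 * p0
  } else if (is.null(p1)) {
    stop("'p1' is required for variant 'depression_facilitation'")
  }
  obj <- structure(
    list(n = as.integer(n), tau_D = as.numeric(tau_D),
         tau_F = as.numeric(tau_F), p0 = as.numeric(p0),
         p1 = as.numeric(p1), mu_a = as.numeric(mu_a),
         sigma_a = as.numeric(sigma_a), sigma_b = as.numeric(sigma_b),
         variant = variant),
    class = "synq_params")
  validate_params(obj)
  obj
}

#' @rdname model_params
#' @param x object to validate / test.
#' @export
validate_params <- function(x) {
  stopifnot(inherits(x, "synq_params"))
  with(x, {
    if (length(n) != 1L || is.na(n) || n < 1L) stop("'n' must be an integer >= 1")
    if (!is.finite(tau_D) || tau_D <= 0) stop("'tau_D' must be > 0")
    if (!is.finite(tau_F) || tau_F <= 0) stop("'tau_F' must be > 0")
    if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop("'p0' must lie in (0, 1)")
    if (!is.finite(p1) || p1 >= 1) stop("'p1' must lie in [p0, 1)")
    if (p1 < p0) stop("'p1' must be >= 'p0'")
    if (variant == "depression_facilitation" && p1 <= p0)
      stop("'p1' must exceed 'p0' for variant 'depression_facilitation'")
    if (variant == "depression_only" && p1 != p0)
      stop("'p1' must equal 'p0' for variant 'depression_only'")
    if (!is.finite(mu_a) || !is.finite(sigma_a) || sigma_a <= 0 || mu_a <= sigma_a)
      stop("'mu_a' must be greater than 'sigma_a' and both positive")
    if (!is.finite(sigma_b) || sigma_b <= 0) stop("'sigma_b' must be > 0")
  })
  invisible(x)
}

#' @rdname model_params
#' @export
is_model_params <- function(x) inherits(x, "synq_params")

#' @export
print.synq_params <- function(x, ...) {
  cat("Synaptic model parameters (", x$variant, ")\n", sep = "")
  cat(sprintf("  n = %d sites; tau_D = %g s; tau_F = %g s\n",
              x$n, x$tau_D, x$tau_F))
  cat(sprintf("  p0 = %g; p1 = %g\n", x$p0, x$p1))
  cat(sprintf("  mu_a = %g mV; sigma_a = %g mV; sigma_b = %g mV\n",
              x$mu_a, x$sigma_a, x$sigma_b))
  invisible(x)
}

#' Fig.-style reference parameter set used throughout examples and tests
#'
#' A frequently used ground-truth parameter set for synthetic-data
#' experiments: `n = 7`, `tau_D = 0.25` s, `tau_F = 0.2` s, `p0 = 0.6`,
#' `p1 = 0.8`, `mu_a = 0.25` mV, `sigma_a = 0.1` mV, `sigma_b = 0.05` mV.
#'
#' @param n optional override of the release-site count (e.g. 35 for the
#'   high-`n` regime).
#' @param p0 optional override of the baseline release probability.
#' @param p1 optional override of the facilitated release probability.
#' @return A `"synq_params"` object.
#' @export
reference_params <- function(n = 7L, p0 = 0.6, p1 = 0.8) {
  model_params(n = n, tau_D = 0.25, tau_F = 0.2, p0 = p0, p1 = p1,
               mu_a = 0.25, sigma_a = 0.1, sigma_b = 0.05,
               variant = "depression_facilitation")
}
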