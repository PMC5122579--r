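PARAM_NAMES <- c("n", "tau_D", "tau_F", "p0", "p1", "mu_a", "sigma_a",
                 "sigma_b")

#' Parameter grid for posterior sampling
#'
#' The posterior is explored on a fixed discretised grid; flat priors
#' over the grid make the acceptance ratio a pure likelihood ratio.
#' Each parameter is either free (a vector of at least two values) or
#' clamped (a single value). The defaults span the parameter ranges used
#' in typical cortical paired recordings with headroom: `n` in 1..50,
#' `p0`/`p1` in 0.05..0.95 step 0.05, `tau_D`/`tau_F` on 40 log-spaced
#' points in 0.02..2 s, `mu_a` in 0.02..1 mV, `sigma_a` in 0.01..0.5 mV
#' and `sigma_b` in 0.005..0.3 mV (30 points each). Constraint
#' predicates (`p0 < p1`, `mu_a > sigma_a`) are enforced by proposal
#' rejection during sampling, not by grid construction.
#'
#' For `variant = "depression_only"` the facilitated probability is tied
#' (`p1 = p0`) and `tau_F` is inert, so both are dropped from the free
#' set; for `"facilitation_doubling"`, `p1 = 2 p0` is derived and not
#' free.
#'
#' @param n,tau_D,tau_F,p0,p1,mu_a,sigma_a,sigma_b numeric vectors of
#'   grid values (a single value clamps the parameter); `NULL` selects
#'   the default grid described above.
#' @param variant model variant, as in [model_params()].
#' @return an object of class `"synq_grid"`.
#' @export
parameter_grid <- function(n = NULL, tau_D = NULL, tau_F = NULL,
                           p0 = NULL, p1 = NULL, mu_a = NULL,
                           sigma_a = NULL, sigma_b = NULL,
                           variant = c("depression_facilitation",
                                       "depression_only",
                                       "facilitation_doubling")) {
  variant <- match.arg(variant)
  logspace <- function(a, b, k) exp(seq(log(a), log(b), length.out = k))
  vals <- list(
    n = if (is.null(n)) 1:50 else as.numeric(n),
    tau_D = if (is.null(tau_D)) logspace(0.02, 2, 40) else as.numeric(tau_D),
    tau_F = if (is.null(tau_F)) logspace(0.02, 2, 40) else as.numeric(tau_F),
    p0 = if (is.null(p0)) seq(0.05, 0.95, by = 0.05) else as.numeric(p0),
    p1 = if (is.null(p1)) seq(0.05, 0.95, by = 0.05) else as.numeric(p1),
    mu_a = if (is.null(mu_a)) seq(0.02, 1, length.out = 30) else as.numeric(mu_a),
    sigma_a = if (is.null(sigma_a)) seq(0.01, 0.5, length.out = 30) else as.numeric(sigma_a),
    sigma_b = if (is.null(sigma_b)) seq(0.005, 0.3, length.out = 30) else as.numeric(sigma_b))
  for (nm in PARAM_NAMES) {
    v <- vals[[nm]]
    if (length(v) < 1 || length(v) > 256)
      stop("grid for '", nm, "' must have 1..256 points")
    if (any(!is.finite(v)) || any(diff(v) <= 0))
      stop("grid for '", nm, "' must be finite and strictly increasing")
    if (any(v <= 0)) stop("grid for '", nm, "' must be positive")
  }
  if (any(vals$n != round(vals$n))) stop("'n' grid must be integer-valued")
  if (variant != "depression_facilitation") {
    vals$p1 <- vals$p0[1]  # derived, placeholder only
    if (variant == "depression_only" && is.null(tau_F))
      vals$tau_F <- vals$tau_F[1]  # inert under depression-only dynamics
  }
  free <- vapply(PARAM_NAMES, function(nm) length(vals[[nm]]) > 1, logical(1))
  if (variant != "depression_facilitation") free["p1"] <- FALSE
  structure(list(values = vals, variant = variant, free = free),
            class = "synq_grid")
}

#' @export
print.synq_grid <- function(x, ...) {
  cat("Parameter grid (", x$variant, ")\n", sep = "")
  for (nm in PARAM_NAMES) {
    v <- x$values[[nm]]
    tag <- if (x$free[nm]) sprintf("%d points in [%g, %g]", length(v),
                                   min(v), max(v))
           else if (nm == "p1" && x$variant != "depression_facilitation")
             "derived from p0"
           else sprintf("clamped at %g", v[1])
    cat(sprintf("  %-8s %s\n", nm, tag))
  }
  invisible(x)
}

variant_code <- function(variant) {
  match(variant, c("depression_only", "depression_facilitation",
                   "facilitation_doubling")) - 1L
}

grid_index_of <- function(grid, values) {
  idx <- integer(length(PARAM_NAMES))
  for (j in seq_along(PARAM_NAMES)) {
    nm <- PARAM_NAMES[j]
    if (!grid$free[nm]) { idx[j] <- 0L; next }
    if (is.null(values[[nm]]))
      stop("start point must specify free parameter '", nm, "'")
    i <- which.min(abs(grid$values[[nm]] - values[[nm]]))
    idx[j] <- i - 1L
  }
  idx
}

#' Grid Metropolis-Hastings sampling of the posterior
#'
#' Random-walk Metropolis-Hastings over the parameter grid with flat
#' priors. The chain starts at a uniformly random valid grid point (or a
#' supplied start point); at each step one of the `2 d` axis-neighbour
#' moves is proposed with equal probability (`d` = number of free
#' parameters); proposals falling off the grid or violating the
#' constraint predicates are rejected (the chain stays put); otherwise
#' the move is accepted with probability `min(1, exp(delta log-lik))`.
#' Log-likelihoods are memoised per grid point, and amplitude-density
#' tables are shared across grid points that differ only in the dynamic
#' parameters, so long chains are cheap. A fixed seed gives a
#' bit-identical chain.
#'
#' @param dataset a [sweep_dataset()] object.
#' @param grid a [parameter_grid()] object.
#' @param mode `"correlated"` (exact likelihood) or `"uncorrelated"`
#'   (factorised baseline).
#' @param n_samples total number of iterations.
#' @param burn_in iterations discarded from the front (default 10%).
#' @param seed integer seed.
#' @param start optional named list of parameter values for the initial
#'   point (each mapped to the nearest grid value); `NULL` for a random
#'   valid start.
#' @return an object of class `"synq_chain"`: a list with `samples`
#'   (matrix, one row per kept iteration, columns the eight parameters),
#'   `loglik`, `acceptance_rate`, `seed`, `mode`, and the `grid`.
#' @export
metropolis_hastings <- function(dataset, grid,
                                mode = c("correlated", "uncorrelated"),
                                n_samples, burn_in = floor(0.1 * n_samples),
                                seed = 1L, start = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "synq_dataset"), inherits(grid, "synq_grid"),
            n_samples > burn_in, burn_in >= 0)
  free_dims <- which(grid$free) - 1L
  if (length(free_dims) == 0) stop("grid has no free parameters")
  start_idx <- if (!is.null(start)) grid_index_of(grid, start) else NULL
  set.seed(seed)
  res <- .mh_sampler_cpp(lapply(dataset$sweeps, `[[`, "times"),
                         lapply(dataset$sweeps, `[[`, "amplitudes"),
                         unname(grid$values[PARAM_NAMES]),
                         as.integer(free_dims),
                         variant_code(grid$variant),
                         mode == "correlated",
                         as.integer(n_samples), as.integer(burn_in),
                         start_idx)
  colnames(res$samples) <- PARAM_NAMES
  structure(list(samples = res$samples, loglik = as.numeric(res$loglik),
                 acceptance_rate = res$accepted / n_samples,
                 n_evals = res$n_evals, n_samples = n_samples,
                 burn_in = burn_in, seed = seed, mode = mode, grid = grid),
            class = "synq_chain")
}

#' @export
print.synq_chain <- function(x, ...) {
  cat(sprintf(
    "MH chain: %d kept samples (%s likelihood), acceptance rate %.2f\n",
    nrow(x$samples), x$mode, x$acceptance_rate))
  invisible(x)
}

chain_param_values <- function(chain, param) {
  grid <- chain$grid
  if (param == "p1" && grid$variant == "depression_only")
    return(grid$values$p0)
  if (param == "p1" && grid$variant == "facilitation_doubling")
    return(2 * grid$values$p0)
  grid$values[[param]]
}

#' Marginal posterior histogram for one parameter
#'
#' Normalised empirical frequency of the chain over the parameter's grid
#' values.
#'
#' @param chain a `"synq_chain"` from [metropolis_hastings()].
#' @param param parameter name, one of
#'   `n, tau_D, tau_F, p0, p1, mu_a, sigma_a, sigma_b`.
#' @return data frame with columns `value` and `prob` (sums to 1).
#' @export
marginal_posterior <- function(chain, param) {
  stopifnot(inherits(chain, "synq_chain"))
  if (!param %in% PARAM_NAMES) stop("unknown parameter '", param, "'")
  values <- chain_param_values(chain, param)
  i <- match_grid(chain$samples[, param], values)
  prob <- tabulate(i, nbins = length(values)) / nrow(chain$samples)
  data.frame(value = values, prob = prob)
}

match_grid <- function(x, values) {
  i <- match(signif(x, 12), signif(values, 12))
  if (anyNA(i)) stop("sample value not on the parameter grid")
  i
}

#' Pairwise posterior histogram for two parameters
#'
#' @inheritParams marginal_posterior
#' @param paramA,paramB parameter names.
#' @return a matrix of joint frequencies (rows indexed by `paramA` grid
#'   values, columns by `paramB`), summing to 1, with the grid values in
#'   `dimnames`.
#' @export
pairwise_posterior <- function(chain, paramA, paramB) {
  stopifnot(inherits(chain, "synq_chain"))
  for (p in c(paramA, paramB))
    if (!p %in% PARAM_NAMES) stop("unknown parameter '", p, "'")
  va <- chain_param_values(chain, paramA)
  vb <- chain_param_values(chain, paramB)
  ia <- match_grid(chain$samples[, paramA], va)
  ib <- match_grid(chain$samples[, paramB], vb)
  tab <- matrix(0, length(va), length(vb),
                dimnames = list(format(va), format(vb)))
  for (r in seq_along(ia)) tab[ia[r], ib[r]] <- tab[ia[r], ib[r]] + 1
  tab / nrow(chain$samples)
}

#' Maximum a-posteriori estimate from a chain
#'
#' Under flat priors the joint MAP is the visited grid point with the
#' highest recorded log-likelihood (ties broken by first occurrence).
#' `type = "marginal"` instead reports, per parameter, the mode of its
#' marginal histogram -- the two need not coincide.
#'
#' @inheritParams marginal_posterior
#' @param type `"joint"` (default) or `"marginal"`.
#' @return named numeric vector of the eight parameters (plus `loglik`
#'   for the joint MAP).
#' @export
map_estimate <- function(chain, type = c("joint", "marginal")) {
  stopifnot(inherits(chain, "synq_chain"))
  type <- match.arg(type)
  if (type == "joint") {
    i <- which.max(chain$loglik)
    return(c(chain$samples[i, ], loglik = chain$loglik[i]))
  }
  vapply(PARAM_NAMES, function(p) {
    h <- marginal_posterior(chain, p)
    h$value[which.max(h$prob)]
  }, numeric(1))
}

#' Equal-tailed credible interval from a chain marginal
#'
#' Smallest grid span containing at least `level` posterior mass with at
#' most `(1 - level)/2` mass strictly outside each end (tails rounded
#' outward).
#'
#' @inheritParams marginal_posterior
#' @param level credibility level in (0, 1).
#' @return named numeric vector `c(lo, hi)` of grid values.
#' @export
credible_interval <- function(chain, param, level = 0.95) {
  stopifnot(level > 0, level < 1)
  h <- marginal_posterior(chain, param)
  credible_interval_hist(h$value, h$prob, level)
}

credible_interval_hist <- function(values, prob, level) {
  alpha <- (1 - level) / 2
  N <- length(values)
  below <- c(0, cumsum(prob))[seq_len(N)]       # mass strictly below bin i
  above <- rev(c(0, cumsum(rev(prob))))[-1]     # mass strictly above bin i
  lo <- max(which(below <= alpha + 1e-12))
  hi <- min(which(above <= alpha + 1e-12))
  c(lo = values[lo], hi = values[hi])
}

#' Cross-chain convergence check
#'
#' Per-parameter total-variation distance between the marginal
#' histograms of independently initialised chains (maximum over chain
#' pairs), with a pass flag at a configurable threshold.
#'
#' @param chains list of at least two `"synq_chain"` objects sharing a
#'   grid.
#' @param threshold maximum acceptable total-variation distance.
#' @return list with `tv` (named vector over free parameters), `pass`
#'   (logical) and `threshold`.
#' @export
convergence_check <- function(chains, threshold = 0.1) {
  if (length(chains) < 2) stop("need at least two chains")
  free <- PARAM_NAMES[chains[[1]]$grid$free]
  tv <- vapply(free, function(p) {
    hs <- lapply(chains, function(ch) marginal_posterior(ch, p)$prob)
    mx <- 0
    for (i in seq_along(hs)) for (j in seq_len(i - 1))
      mx <- max(mx, 0.5 * sum(abs(hs[[i]] - hs[[j]])))
    mx
  }, numeric(1))
  list(tv = tv, pass = all(tv <= threshold), threshold = threshold)
}

#' Exhaustive grid posterior (MCMC oracle)
#'
#' Evaluates the likelihood at every valid grid point and normalises --
#' feasible only for small grids (guarded at 1e6 points) but exact, so
#' it serves as the reference law the sampler's long-run occupancy must
#' match.
#'
#' @inheritParams metropolis_hastings
#' @return data frame with one row per valid grid point: the eight
#'   parameter columns, `loglik` and normalised posterior `prob`.
#' @export
exhaustive_posterior <- function(dataset, grid,
                                 mode = c("correlated", "uncorrelated")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "synq_dataset"), inherits(grid, "synq_grid"))
  free <- PARAM_NAMES[grid$free]
  sizes <- vapply(free, function(nm) length(grid$values[[nm]]), integer(1))
  if (prod(sizes) > 1e6) stop("grid larger than the 1e6-point guard")
  pts <- expand.grid(lapply(free, function(nm) grid$values[[nm]]),
                     KEEP.OUT.ATTRS = FALSE)
  names(pts) <- free
  theta0 <- vapply(PARAM_NAMES, function(nm) grid$values[[nm]][1], numeric(1))
  times <- lapply(dataset$sweeps, `[[`, "times")
  amps <- lapply(dataset$sweeps, `[[`, "amplitudes")
  full <- matrix(rep(theta0, each = nrow(pts)), nrow(pts), 8,
                 dimnames = list(NULL, PARAM_NAMES))
  for (nm in free) full[, nm] <- pts[[nm]]
  if (grid$variant == "depression_only") full[, "p1"] <- full[, "p0"]
  if (grid$variant == "facilitation_doubling") full[, "p1"] <- 2 * full[, "p0"]
  valid <- full[, "p1"] < 1 & full[, "mu_a"] > full[, "sigma_a"]
  if (grid$variant == "depression_facilitation")
    valid <- valid & full[, "p0"] < full[, "p1"]
  full <- full[valid, , drop = FALSE]
  if (nrow(full) == 0) stop("no valid grid points")
  ll <- vapply(seq_len(nrow(full)), function(i)
    .loglik_dataset_cpp(times, amps, full[i, ], mode == "correlated"),
    numeric(1))
  w <- exp(ll - max(ll))
  out <- as.data.frame(full)
  out$loglik <- ll
  out$prob <- w / sum(w)
  out
}

#' Posterior summary
#'
#' Collects the joint and marginal MAP estimates, equal-tailed credible
#' intervals for every free parameter, and the acceptance rate.
#'
#' @inheritParams credible_interval
#' @return an object of class `"synq_summary"` (a list).
#' @export
posterior_summary <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "synq_chain"))
  free <- PARAM_NAMES[chain$grid$free]
  ci <- lapply(free, function(p) credible_interval(chain, p, level))
  names(ci) <- free
  structure(list(map = as.list(map_estimate(chain, "joint")),
                 marginal_mode = as.list(map_estimate(chain, "marginal")),
                 credible_intervals = lapply(ci, as.list),
                 level = level, mode = chain$mode, seed = chain$seed,
                 acceptance_rate = chain$acceptance_rate,
                 n_samples = chain$n_samples, burn_in = chain$burn_in),
            class = "synq_summary")
}

#' @export
print.synq_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%s likelihood, %d samples)\n",
              x$mode, x$n_samples))
  cat(sprintf("  joint MAP loglik = %.3f\n", x$map$loglik))
  for (p in names(x$credible_intervals)) {
    ci <- x$credible_intervals[[p]]
    cat(sprintf("  %-8s MAP %-10g %g%% CI [%g, %g]\n", p, x$map[[p]],
                100 * x$level, ci$lo, ci$hi))
  }
  invisible(x)
}
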