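---
title: "Correlated quantal inference: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated quantal inference: model, numerics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

This vignette is the package's own account of the science it
implements: the generative model and its assumptions, the exact
likelihood and its numerics, the sampler, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the design was genuinely open. It states no empirical result that
the test suite does not itself compute.

## 1. The generative model

A synapse has `n` statistically independent release sites. Site
occupancy is binary; all sites start stocked (the experimental
protocols this package targets leave 10 s or more between sweeps, long
enough for full pool recovery, which is also what makes sweeps
independent). On the *m*-th presynaptic spike each stocked site
releases independently with probability $u_m$; each site left empty
restocks before the next spike with probability $g_m$. Both schedules
are *deterministic* functions of the spike times and the parameters —
this is the property that the whole likelihood construction rests on.

For the depression–facilitation variant used throughout:

$$u_1 = p_0, \qquad
  u_m^{+} = u_m + (1-u_m)\frac{p_1-p_0}{1-p_0}, \qquad
  u_{m+1} = p_0 + (u_m^{+}-p_0)\,e^{-T_m/\tau_F},$$

$$g_m = 1 - e^{-T_m/\tau_D},$$

with $T_m$ the interspike interval. The $(1-u)$ prefactor of the
facilitation jump caps the release probability below one; an isolated
spike takes $u$ from $p_0$ to exactly $p_1$. All dynamics are
event-driven with exact exponentials — no time discretisation anywhere,
including in the simulator, whose per-interval restock is a single
Bernoulli draw with probability $g_m$ (exact for a constant-rate
Poissonian restock process).

Three variants share this recursion through the value of $p_1$:
depression-only ($p_1 = p_0$, facilitation vanishes identically),
depression–facilitation ($p_0 < p_1 < 1$), and a reduced facilitation
model with $p_1 = 2p_0$ tied at construction (one fewer free
parameter). Because a variant enters the likelihood only through its
$(u, g)$ schedules, further dynamics models (release-independent
depression, frequency-dependent recovery, …) can be added at the
schedule level without touching the likelihood code; those models are
deliberately out of scope here.

When $k$ vesicles release, the observed amplitude is
$A = \psi + \phi$: $\psi$ is a sum of $k$ i.i.d. gamma quanta — hence
itself gamma with shape $\beta = k\mu_a^2/\sigma_a^2$ and rate
$\lambda = \mu_a/\sigma_a^2$ — and $\phi$ is zero-mean Gaussian noise
with s.d. $\sigma_b$. The model requires $\mu_a > \sigma_a$ (so a zero
amplitude is not the most likely single-vesicle response); this
innocuous-looking invariant matters numerically below. Negative
observed amplitudes are legal (noise-dominated events); $\psi$ itself
is non-negative by construction.

## 2. The exact likelihood as a matrix product

The naive likelihood sums over all $(n+1)^M$ release sequences. The
occupancy $y_m$ just before each spike is, however, Markov: release
given occupancy is $\mathrm{Binom}(k; y, u_m)$ and restock of the
$n-y+k$ empty sites is again binomial in $g_m$. Conditioning on $y$
turns the sum into a product of $(n+1)\times(n+1)$ kernels,

$$L = \langle L_M |\, Q_{M-1}\cdots Q_1 \,| R_0\rangle, \qquad
  Q_m[y',y] = \sum_{k=0}^{y} P(y'|k,y;g_m)\, P[A_m|k]\,
  \mathrm{Binom}(k;y,u_m),$$

with $|R_0\rangle = \delta_{y,n}$. The cost is
$O(M\,n^3)$ — linear in train length. Two numerical
choices:

* **Scaling.** After each kernel application the state vector is
  divided by its sum and the log accumulated (standard forward-algorithm
  scaling). This was chosen over extended-precision arithmetic for
  speed; the test suite verifies that with unit observation weights the
  scaled product conserves probability to $10^{-12}$ over 50 spikes and
  that 1000-spike trains stay finite.
* **Exact binomials.** Binomial coefficients come from a Pascal table
  (exact in doubles far beyond the grid's maximum $n = 50$), combined
  with precomputed power tables per spike, so kernel entries are exact
  products before observation weighting.

The package carries *three* independent routes to the same quantity,
and their agreement is the backbone of the test suite: the C++ forward
algorithm (fast path), a pure-R reference built from the exported
kernel constructors, and a brute-force oracle that enumerates per-site
histories (release/hold and restock/stay branches per site, convolved
over `n` i.i.d. sites) without ever forming a transition matrix. The
oracle agrees with the forward algorithm to $10^{-10}$ relative over
randomised parameters, regular and Poisson trains.

The **uncorrelated baseline** replaces the joint release law by its
per-spike marginals: amplitudes are scored independently given the
spike times only. The specification left open whether the marginal
$P(k_m)$ should come from exact occupancy-distribution propagation or
from the mean-field occupancy recursion; for this model class the
question dissolves — without amplitude conditioning the sites are
i.i.d., so the occupancy law is *exactly*
$\mathrm{Binom}(n, \langle x\rangle_m)$ and the two routes coincide.
Both are implemented (propagation is the default), and their equality
to $10^{-10}$ is a regression test rather than an assumption.

## 3. The observation density

$P[A|k]$ for $k \ge 1$ is the convolution integral of the gamma and
Gaussian densities. The integrand's log is
$(\beta-1)\log y - \lambda y - (A-y)^2/2\sigma_b^2$: strictly concave
whenever $\beta > 1$ — and $\mu_a > \sigma_a$ guarantees
$\beta = k\mu_a^2/\sigma_a^2 > 1$ for every $k \ge 1$, so the
integrand is always unimodal and log-concave with no endpoint
singularity. The implementation therefore solves the quadratic for the
mode analytically, sets a window of $\pm 12$ curvature-based standard
deviations (clamped at zero), and applies a fixed 64-node
Gauss–Legendre rule in log space with log-sum-exp accumulation.
Accuracy against `stats::integrate` at `rel.tol = 1e-10` is at the
$10^{-14}$ level across amplitudes from deep in the left noise tail to
far above the bulk; a Monte-Carlo kernel-density oracle independently
confirms the convolution at the percent level. `k = 0` uses the
analytic Gaussian branch. An adaptive-quadrature fallback for
$\beta < 1$ was considered and found unreachable in-model; the
adaptive route is retained as the exported reference implementation
(`amplitude_density_reference`) rather than as a live branch.

Within one likelihood evaluation the density table over
$(A_m, k)$ is computed once and shared by all kernels; within one
sampler run the tables are additionally shared across all grid points
that have the same quantal parameters (see below).

## 4. The sampler

The posterior is explored on a fixed grid with flat priors. Proposals
move to one of the $2d$ axis neighbours with equal probability; moves
off the grid or into the constraint-violating region ($p_1 \ge 1$,
$p_0 \ge p_1$ for the facilitation variant, $\mu_a \le \sigma_a$) are
rejected with the chain staying put, which keeps the proposal law
exactly symmetric; valid moves are accepted with probability
$\min(1, e^{\Delta \log L})$. Randomness comes from R's generator, so
`set.seed` gives bit-identical chains.

Defaults the literature leaves unstated, chosen once:

| parameter | grid | rationale |
|---|---|---|
| `n` | 1..50 step 1 | spans reported site counts at cortical connections with headroom |
| `p0`, `p1` | 0.05..0.95 step 0.05 | full usable probability range; constraints by rejection |
| `tau_D`, `tau_F` | 40 log-spaced points, 0.02..2 s | timescales are scale parameters; log spacing gives uniform relative resolution |
| `mu_a` | 0.02..1 mV, 30 points | sub-mV quantal sizes typical of central synapses |
| `sigma_a` | 0.01..0.5 mV, 30 points | below `mu_a` by the model invariant |
| `sigma_b` | 0.005..0.3 mV, 30 points | recording-noise range for whole-cell data |

Burn-in defaults to 10% of the requested samples; no thinning (the
histograms over a fixed grid are insensitive to autocorrelation given
chain length). The MAP is reported as the best *visited* point (and,
separately, as per-parameter marginal modes, since the two readings of
"maximum a-posteriori" differ in general). Equal-tailed credible
intervals round their tails outward on the discrete histogram, so a
reported 95% interval never contains less than 95% of the mass.

Because the state space is a grid, the sampler memoises the
log-likelihood per visited grid point and shares amplitude-density
tables across points that differ only in the dynamic parameters
($n$, $\tau_D$, $\tau_F$, $p_0$, $p_1$ moves reuse the cached
densities). A $2\times10^5$-step chain on the full eight-parameter grid
against 5 sweeps × 30 spikes costs roughly 15 s on one CPU —
this is an implementation decision only; it changes no sampled value.

Correctness is checked two ways: on tiny problems the chain's long-run
occupancy matches the exhaustive-grid posterior (total variation
< 0.05 from opposite corner initialisations, $10^6$ steps), and
two-point/flat-direction chains reproduce their known stationary laws.
Multi-chain convergence is monitored by per-parameter total-variation
distance between marginals (`convergence_check`), as a sampler on a
bounded grid admits no scale-reduction statistic worth the name.

## 5. The synthetic-data generator

`simulate_sweep` draws exactly the process the likelihood integrates
over: per-site Bernoulli release at the scheduled $u_m$, per-site
Bernoulli restock at $g_m$, a single gamma draw with shape
$k\mu_a^2/\sigma_a^2$ for the quantal sum (exact by gamma additivity,
in place of summing $k$ draws), plus Gaussian noise. The root seed
spawns one child seed per sweep, so sweep $i$ is invariant to the total
sweep count — the property that lets the interval-width experiments
grow a dataset from 1 to 8 sweeps while keeping the first sweep fixed.

Default experimental regimes mirror the published protocols: regular or
Poisson trains of 5–30 spikes at 20–50 Hz, 1–8 sweeps, ground truth
$n = 7$, $\tau_D = 0.25$ s, $\tau_F = 0.2$ s, $p_0 = 0.6$, $p_1 = 0.8$,
$\mu_a = 0.25$ mV, $\sigma_a = 0.1$ mV, $\sigma_b = 0.05$ mV (exposed
as `reference_params()`), with $n = 35$, $p_0 = 0.6$ for the high-`n`
regime.

What the generator does **not** emulate — and therefore what a green
recovery test does not establish — includes: amplitude extraction from
raw voltage traces (inputs here are already-deconvolved amplitudes, so
deconvolution error is outside the model), drift in recording
conditions across sweeps, amplitude-correlated or non-Gaussian noise,
receptor desensitisation or postsynaptic saturation, and any
activity-dependence of the restock rate. Recovery results say the
method inverts its own generative model from realistic amounts of data,
not that the model is a complete account of a biological synapse.

## 6. What the acceptance experiments establish

The test suite's acceptance block mirrors the published validation
experiments at reduced computational scale:

* full-grid recovery from 5 sweeps × 30 spikes at 30 Hz: the true
  $n$, $\tau_D$, $p_0$, $p_1$, $\mu_a$, $\sigma_b$ fall inside their
  95% intervals in at least 8 of 10 seeded replicates, with $\tau_F$
  and $\sigma_a$ explicitly permitted to stay broad (they are weakly
  identified under regular stimulation; Poisson stimulation and very
  high rates respectively are the protocol-level remedies). Sampler
  length is $2\times10^5$ per seed — the stated reduced floor relative
  to the $10^6$ used for the published figures.
* the high-`n` (35-site), sparse-data regime: 95% intervals for `n`
  from the correlated likelihood are on average no wider than from the
  uncorrelated one, the gap closing as sweeps grow from 1 to 8; and the
  $n$–$p_0$ posterior correlation is negative in at least 8 of 10
  replicates. Here the sampler is shortened to $2\times10^4$ steps and
  only $n$ and $p_0$ are left free (the other parameters are clamped at
  truth) — the scaled-down reading of the corresponding figure, chosen
  to keep the whole suite inside a CI budget.

## 7. Known limitations

* The initial state is fixed at fully stocked; inferring the initial
  occupancy (relevant for in-vivo trains without rest periods) is out
  of scope.
* Grids cap $n$ at 50 and each dimension at 256 points; the sampler
  addresses grid points with 8-bit indices per dimension.
* The uncorrelated baseline shares the observation model and schedules
  with the exact likelihood; it isolates the effect of discarding
  serial correlations only, not of other modelling differences between
  published approximate methods.
* `facilitation_doubling` requires $p_0 < 0.5$ by construction; the
  grid constructor does not prune $p_0 \ge 0.5$ points, they are simply
  rejected during sampling.
* Likelihood derivatives (for gradient-based samplers) and marginal
  likelihoods (for model comparison) are not provided.
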