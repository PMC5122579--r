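# synquant

Bayesian quantal analysis of synaptic amplitude trains that keeps the
serial correlations between vesicle-release events.

## The problem

A chemical synapse transmits with `n` independent release sites. On
arrival of the *m*-th presynaptic spike each docked vesicle is released
with probability `u_m`; an emptied site is restocked before the next
spike with probability `g_m`. Released vesicles produce a postsynaptic
potential whose amplitude is built up from gamma-distributed quanta
(mean `mu_a`, s.d. `sigma_a`) plus Gaussian recording noise (`sigma_b`).
Short-term plasticity makes `u_m` and `g_m` history dependent: vesicle
depletion depresses transmission on a timescale `tau_D`, while residual
calcium transiently facilitates release, raising `u` from its baseline
`p0` towards a facilitated value `p1` that decays back with timescale
`tau_F` (the classic depression–facilitation dynamics of the
Tsodyks–Markram family).

Because successive responses share the same depleting vesicle pool,
amplitudes within a train are *correlated*, and those correlations carry
real information — especially for synapses with few sites, high release
probability or slow restock, and for experiments with only one or a few
sweeps. Inference methods that treat amplitudes as independent discard
that information. The difficulty is that the exact likelihood of an
amplitude train naively costs `(n+1)^M` terms for `M` spikes.

## The method

The occupancy `y` (number of stocked sites just before a spike) is a
Markov chain on `{0, …, n}`. Conditioning on it factorises the train
likelihood into a **matrix product** — a forward algorithm:

    L(A_M, …, A_1 | θ) = ⟨L_M| Q_{M-1} ⋯ Q_1 |R_0⟩

with `|R_0⟩ = δ_{y,n}` (fully stocked start),

    Q_m[y', y] = Σ_k P(y'|k, y; g_m) · P[A_m|k] · Binom(k; y, u_m)

and `⟨L_M|` the matching final row vector. Release given occupancy is
binomial; restock of the empty sites is binomial; `P[A|k]` is the
gamma–Gaussian convolution observation density. The cost is linear in
`M`, and per-step rescaling keeps everything finite for arbitrarily long
trains. The eight parameters

    θ = {n, tau_D, tau_F, p0, p1, mu_a, sigma_a, sigma_b}

are then sampled on a discretised grid by Metropolis–Hastings with flat
priors (axis-neighbour proposals, rejection of constraint-violating
moves). An uncorrelated baseline likelihood (amplitudes independent
given spike times), a brute-force enumeration oracle, and an exact
stochastic simulator are included; the simulator, the forward
likelihood and the enumeration oracle are pinned against each other in
the test suite.

## Worked example

Five simulated sweeps of 30 regular spikes at 30 Hz from a ground-truth
synapse with `n = 7`, `tau_D = 0.25 s`, `tau_F = 0.2 s`, `p0 = 0.6`,
`p1 = 0.8`, `mu_a = 0.25 mV`, `sigma_a = 0.1 mV`, `sigma_b = 0.05 mV`
(shipped as `inst/extdata/example_sweeps.csv`):

```r
library(synquant)
ds <- read_sweeps(system.file("extdata", "example_sweeps.csv",
                              package = "synquant"))
chain <- metropolis_hastings(ds, parameter_grid(), mode = "correlated",
                             n_samples = 2e5, burn_in = 2e4, seed = 1)
posterior_summary(chain)
```

prints (about 15 s on one CPU):

```
Posterior summary (correlated likelihood, 200000 samples)
  joint MAP loglik = 35.560
  n        MAP 8          95% CI [6, 13]
  tau_D    MAP 0.302355   95% CI [0.212164, 0.430887]
  tau_F    MAP 1.77725    95% CI [0.0225067, 1.77725]
  p0       MAP 0.65       95% CI [0.4, 0.8]
  p1       MAP 0.95       95% CI [0.5, 0.95]
  mu_a     MAP 0.222759   95% CI [0.155172, 0.290345]
  sigma_a  MAP 0.128276   95% CI [0.0944828, 0.195862]
  sigma_b  MAP 0.0456897  95% CI [0.0456897, 0.0660345]
```

Every well-identified parameter's 95% credible interval contains its
true value; the facilitation timescale `tau_F` and the quantal spread
`sigma_a` remain broad, which is the expected behaviour for this
protocol (a minute of regular stimulation constrains them weakly). The
pairwise posterior shows the characteristic trade-off between site
count and release probability:

```r
cor(chain$samples[, "n"], chain$samples[, "p0"])
#> -0.3238174
```

The same pipeline is scriptable from a shell via
`Rscript inst/cli/synquant.R {simulate|infer|compare|summarize} …`.

## Package layout

- `R/dynamics.R` — deterministic release/restock schedules, mean
  occupancy, expected amplitudes
- `R/amplitude.R` — gamma–Gaussian observation density (fast
  Gauss–Legendre path plus an adaptive-quadrature reference)
- `R/likelihood.R` — matrix-product likelihood, uncorrelated baseline,
  brute-force enumeration oracle
- `R/inference.R` — parameter grids, grid Metropolis–Hastings,
  posterior summaries, exhaustive-grid oracle
- `R/simulate.R` — stochastic per-site synapse simulator and protocols
- `R/cli_io.R` — sweep/posterior/summary file formats, JSON config, CLI
- `src/` — the numerical core (density, forward algorithm, sampler)
- `vignettes/correlated-quantal-inference.Rmd` — methods notes
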