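---
title: "Generative quantal analysis of repetitive synaptic transmission"
author: "stpem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative quantal analysis of repetitive synaptic transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpem)
```

## The model

`stpem` models a chemical synaptic connection as a collection of `N`
identical, independent release sites (the stochastic Tsodyks–Markram quantal
model).  A site is *release competent* when a vesicle is docked to it.  Upon
a presynaptic spike each competent site releases its vesicle independently
with probability `u(t)`; between spikes, an empty site refills with constant
probability per unit time `1/tau_D`, so the probability of docking within an
interval `Delta` is `l(Delta) = 1 - exp(-Delta/tau_D)`.  The release
probability facilitates: it jumps at each spike and relaxes back to its
baseline `U` with time constant `tau_F`, which gives the per-spike recursion

    u_1 = U,   u_{k+1} = U + u_k (1 - U) exp(-Delta_k / tau_F).

The postsynaptic response to a single vesicle is a right-skewed random
amplitude with mean `q` (quantal size) and SD `sigma_q`, modelled as an
inverse Gaussian; responses to `m` vesicles sum linearly and are again
inverse Gaussian with mean `m q` and variance `m sigma_q^2`.  Recorded
amplitudes additionally carry Gaussian baseline noise of SD `sigma_n`.
Times are in milliseconds and amplitudes in millivolts throughout.

The mean response to spike `k` is `Rbar_k = A u_k x_k`, where `A = N q` is
the absolute synaptic efficacy and `x_k` the mean site occupancy with its
own depletion/refill recursion.  Only the full stochastic model — not the
mean — is used for estimation.

## Exact likelihood and EM

Writing `S-_k`, `S+_k` for the number of competent sites immediately before
and after spike `k`, the joint probability of the observed amplitudes and
the hidden site counts factorizes into an initial condition (all sites
competent at rest), binomial release transitions, inverse-Gaussian (noise
convolved) emissions, and binomial docking transitions.  The marginal
likelihood of a response train is computed exactly by forward–backward
recursions over the `N + 1` hidden states (`forward_pass()`), with per-spike
scaling constants against underflow; `brute_force_log_likelihood()`
enumerates all hidden paths on tiny instances and is used as the oracle in
the test suite.

Maximum-likelihood estimation uses EM over the hidden site counts
(`fit_fixed_N()`).  The E step (`e_step()`) computes the posterior pair
distribution of `(S-_k, S+_k)` for every spike and, with baseline noise, the
posterior moments `E[y]` and `E[1/y]` of the latent noiseless response `y`.
The M step is exact:

* `q_new = sum E[y] / sum <m>` — augmenting the latent state with `y` makes
  the coupled stationarity conditions for `(q, sigma_q)` collapse to this
  closed form, with a companion quadratic form for `sigma_q^2`;
* `tau_D` maximizes the docking part of the auxiliary function (1-D,
  bracketed in log space);
* `(U, tau_F)` jointly maximize the release part (the two conditions are
  coupled through the facilitation recursion and must be solved
  simultaneously; bounded quasi-Newton on logit/log scales).

Because every M-step component maximizes its own part of the auxiliary
function, the log-likelihood is non-decreasing.  `N` is discrete and is
selected by scanning (`fit_em()`, default `N` in 1..100) and keeping the
maximum-likelihood `N`; exact ties go to the smaller `N`.

## Numerical choices

* **Emission integrals.**  With baseline noise the emission density is the
  integral of an inverse-Gaussian times a Gaussian.  The integrand is
  localized by a safeguarded Newton search for its mode; composite
  Gauss–Legendre panels cover the mode (±12 posterior widths), the skewed
  right tail (to +30 widths), and, for heavy-tailed quantal distributions,
  the Gaussian noise window.  The likelihood API uses 60 nodes per panel,
  EM uses 40; states whose emission peak lies more than 30 log-units below
  the per-spike maximum (posterior weight < 1e-13) are replaced by their
  Laplace approximation.  The public `emission_density()` uses adaptive
  quadrature (`stats::integrate`, rel.tol 1e-10) and serves as an
  independent reference in the tests.
* **Acceleration and monotonicity.**  Plain EM crawls on the ridge coupling
  `N`-compensating parameters; `fit_fixed_N()` therefore uses safeguarded
  squared extrapolation (SQUAREM-style): an extrapolated step is accepted
  only if it does not decrease the log-likelihood, so the recorded trace is
  monotone like plain EM.  Because the quadrature nodes move with the
  parameters, the surrogate likelihood is exact only to quadrature
  precision; when an M step can no longer improve the likelihood at that
  precision the fit stops at the last accepted iterate.
* **Convergence and restarts.**  Relative log-likelihood tolerance 1e-8,
  at most 500 E-steps, 5 restarts by default.  The facilitation time
  constant has well-separated basins (fast- vs slow-facilitation); the
  first two restarts deterministically probe `tau_F` at 8x and 1/8x the
  initial guess before random log-uniform jitter in [1/3, 3].  Restart
  competition uses short runs (tolerance 1e-4); only the winner is iterated
  to full tolerance.
* **Initialization.**  Method of moments from the first responses (mean and
  variance of the first amplitude give binomial guesses for `U N` and `q`);
  both time constants start at the geometric mean of the observed
  interspike intervals.
* **Bounds.**  `sigma_q` is floored at 1e-4 mV (a point-mass emission is
  degenerate); `tau_D`, `tau_F` live in [1e-2, 1e7] ms; `tau = 0` inputs are
  treated as exact limits in the deterministic recursions.  `sigma_n` is
  treated as known (estimated from pre-response windows by the preprocessing
  module, or supplied) and is not re-estimated, since inference needs it
  whenever release failures occur.
* **Model-order scans.**  `fit_em()` warm-starts EM outward from an anchor
  `N`; the resampling tools use a coarse scan (every third `N`, relaxed
  tolerance, chains stopped after the profile falls 6 log-units below its
  maximum for two consecutive values) followed by a refinement around the
  coarse winner and a final full-tolerance polish at the selected `N`.
  Likelihood profiles over `N` are smooth and unimodal in practice (we have
  not encountered a counterexample in simulation), which is what makes the
  coarse-to-fine scan and early stopping safe.

## The synthetic-data generator

`simulate_dataset()` draws hidden paths and amplitudes from the generative
model under three stimulation protocols: `regular` trains of `n` spikes at
interval `T` with a recovery spike `T_rec = T + 500` ms after the train
(the standard paired-recording protocol); `poisson`, the same skeleton with
i.i.d. exponential within-train intervals of mean `T` (the recovery interval
stays fixed at `T + 500` ms — a convention choice, since only the within-
train intervals are specified to be random); and `single_sweep`, Poisson
blocks concatenated so the recovery spike of one block is the first spike of
the next, filling a requested recording duration.

The generator's defaults state the world the estimator is validated in:

* the worked-example connection `N = 17`, `q = 0.18`, `sigma_q = 0.06`,
  `U = 0.27`, `tau_D = 202`, `tau_F = 449` with 28 trials of an 8-spike
  20 Hz train plus recovery spike, used for the parametric bootstrap;
* illustrative facilitating (`U = 0.3`, `tau_D = 195`, `tau_F = 570`) and
  depressing (`U = 0.25`, `tau_D = 670`, `tau_F = 15`) connections, both
  `N = 10`, `q = 0.15`, `sigma_q = 0.03`;
* a population sampler (`sample_population_connections()`) drawing from
  truncated normals that match the published population mean ± SD and
  ranges of each parameter for layer-5 pyramidal pairs, with `tau_F`
  clipped below at 10 ms to remain identifiable.

Baseline noise is not printed for the worked-example connection; we fixed
`sigma_n = 0.03` mV once, before any experiment: quantal-noise estimates
are known to degrade when baseline noise is comparable to quantal noise,
and this connection's published bootstrap is well behaved, so its baseline
noise must have been below its `sigma_q = 0.06` mV.  The same value is the
population default.

What a green test does *not* establish: the generator draws from the same
model family the estimator assumes, so recovery tests validate the
machinery, not the model's adequacy for real synapses.  Real recordings add
receptor desensitization at short intervals, heterogeneous release sites,
baseline drift, and non-Gaussian noise, none of which are simulated.

## Validation tools and their scaled-down defaults

* `parametric_bootstrap()` re-estimates all six parameters on synthetic
  replicates; by default it restricts the model-order scan to the
  generating `N` ± 20 (clipped to 1..100) with the coarse-to-fine strategy
  above and one restart chain per `N` (three at the anchor) — the full
  1..100 scan per replicate is available via `full_scan = TRUE` at much
  higher cost.
* `leave_one_out_zout()` computes the predictive tail probability of each
  held-out trial (`z_out`, empirical CDF with the `<=` convention, 2000
  Monte-Carlo trials per fold by default) and tests uniformity by
  Kolmogorov–Smirnov at the conventional 1% level.
* `shuffle_within_position()` destroys within-trial correlations while
  preserving every per-position marginal exactly; fitting shuffled data
  underestimates `tau_D` because the negative correlation between
  consecutive responses (finite-pool depletion) carries the docking
  timescale.  The packaged check of this sign runs with `N` fixed at the
  generating value per replicate: the claim concerns the sign of the
  `tau_D` bias, and a full model-order scan per replicate would add cost
  without touching that sign.
* `fisher_information_matrix()` estimates the expected score outer product
  by Monte Carlo over simulated experiments (the score itself is computed
  by exact derivative recursions propagated alongside the forward pass, not
  by finite differences); `min_relative_errors()` converts it to normalized
  Cramér–Rao bounds `sqrt([I^-1]_jj)/theta_j`.  `N` is discrete and
  excluded from the matrix.  The repetition calculator
  `min_trials_for_precision()` uses a three-standard-error criterion; the
  multiplier 3 is the unique small integer consistent with the usual
  printed repetition counts ("about 80" at 10% precision for CV 0.3,
  ">300" at 5%), and it is configurable.
* `lsf_fit()` is the conventional baseline: weighted least squares of the
  deterministic means over `(A, U, tau_D, tau_F)`; it cannot separate `N`
  from `q`.  `condition_number()` quantifies when this mapping is ill
  posed, using unit weights (so the number depends only on the parameters
  and the protocol), central finite differences of warm-started refits
  (relative step 1e-4), a Gauss–Newton polish so refits are accurate enough
  to differentiate, and the spectral norm.

## Known limitations

* Receptor desensitization, multiple vesicle pools, calcium-dependent
  docking, and heterogeneous release sites are out of scope.
* The noiseless path (`sigma_n = 0`) is valid for simulation but unusable
  for inference when release failures occur (the zero-vesicle emission is a
  point mass).
* EM finds local maxima; the structured restarts cover the empirically
  relevant `tau_F` basins, but pathological data can still defeat them.
* Bootstrap and Fisher-information runs at the packaged scale (hundreds of
  replicates or Monte-Carlo samples) carry sampling error of a few percent;
  they bound, rather than pin down, the estimator's accuracy.
* Estimate correlations from a single-connection bootstrap are dominated by
  the compensation against `N`: `q` and `U` both move opposite to `N`, which
  can make the marginal `U`–`q` correlation positive for an individual
  connection even where the population-averaged value is negative.
  Population-level correlation summaries should pool many connections
  (`average_correlations()`).
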