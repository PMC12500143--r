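---
title: "Assessing early warning signals on stochastic lattice systems"
author: "ewsassess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing early warning signals on stochastic lattice systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewsassess)
```

## The problem

Many ecological and physiological systems sit on a stable branch of a
bistable landscape while an external condition — a harvesting pressure, a
constricting force, a rainfall gradient — drifts slowly.  When the drift
carries the system past a fold bifurcation, the branch disappears and the
state collapses abruptly to the alternative attractor: a critical
transition.  *Early warning signals* (EWS) are statistics of observed data
whose trends may anticipate such transitions through critical slowing down
(CSD): as the dominant eigenvalue of the linearised fast dynamics
approaches zero, perturbations decay more slowly, so variance and
autocorrelation of fluctuations rise.

For spatially extended systems the observation at each time is an entire
lattice snapshot, and there are two families of indicators.  *Temporal*
EWS reduce each snapshot to its spatial mean and track rolling-window
statistics of that univariate series.  *Spatially informed* EWS use the
within-snapshot structure.  This package provides a controlled laboratory
for comparing the two families: a fast–slow stochastic lattice simulator,
the nine indicators, trend quantification with Kendall's τ, significance
via the Hamed–Rao modified Mann–Kendall test, and window-grid / ensemble
assessment machinery.

## The generative model

Each site of an `N × N` lattice carries a state `X[i,j]` obeying

    X <- X + [ f(X, p) + D·Lap(X) ] dt + σ·sqrt(dt)·ξ,     p <- p + ε dt

with a local reaction `f`, nearest-neighbour diffusive coupling through
the periodic 5-point discrete Laplacian, iid standard-normal increments
`ξ` per site, and a bifurcation parameter `p` drifting linearly at the
timescale separation `ε ≪ 1` (Euler–Maruyama scheme).  Initial conditions
are the homogeneous equilibrium of the frozen fast subsystem at the start
of the driver range, solved by Newton iteration (tolerance 1e−12), and
the driver range always extends past the fold so every realisation
contains its transition.

Two reactions are built in:

* **harvest** — the classic overexploitation model
  `f(v, c) = r·v·(1 − v/K) − c·v²/(v² + h₀²)` with `r = 1`, `K = 10`,
  `h₀ = 1`: logistic growth harvested at a saturating rate.  The
  homogeneous fast subsystem has a fold at `c ≈ 2.604`
  (`fold_point()` recovers it by solving `f = 0`, `∂f/∂v = 0`).  Default
  study conditions: `N = 100`, `σ = 0.1`, `ε = 0.001`, `c: 1 → 2.8`,
  40 retained snapshots.
* **bistable** — the fold normal form `f(x, a) = −x³ + x + a`, whose
  lower branch folds at `a = 2/(3√3) ≈ 0.3849`.  It is deliberately tiny
  and fast: the pipeline's test model.

Custom reactions plug in as R functions `f(state, param)`; they integrate
through a pure-R path (R's RNG), while the built-ins run in compiled code
with the package's own xoshiro256++ generator so that a seed fixes the
trajectory bit-for-bit regardless of the calling session's RNG state.

### Parameter choices and numerical safeguards

* **Coupling `D = 0.1`** (per unit time, lattice spacing `h = 1`).  The
  diffusive stencil is stable for `dt ≤ h²/(4D)`; the default `dt = 0.01`
  sits far inside the bound, which is enforced when a run is launched.
* **SLDS vs discretised SPDE.**  An intrinsically discrete lattice model
  uses `(D, σ)` as given; a discretised stochastic reaction–diffusion
  equation on grid spacing `h` uses `D/h²` and `σ/h`.  Both conventions
  sit behind the same integrator (`scaling = "slds" | "spde"`), and the
  equivalence is tested seed-for-seed.
* **Reflecting floor for the harvest model.**  With additive noise the
  region `v < 0` of the harvest reaction is dynamically unstable: once the
  lattice has tipped to the overexploited branch (`v ≈ 0.4`), a
  sufficiently deep noise excursion below zero escapes to −∞ and the
  integration diverges — we observed this reproducibly on the
  post-tipping stretch of the driver range.  Biomass is a density, so
  `harvest_model()` reflects the state at 0.  The barrier lies about five
  stationary standard deviations below the overexploited branch and far
  below the abundant branch, so pre-tipping statistics — everything the
  indicators are computed from — are unaffected.
* **Recording.**  The integrator records every `record_every`-th step
  (plus the initial and final states) instead of materialising every
  Euler step; a full raw harvest trajectory would occupy ~14 GB.  The
  recorded stack is then thinned by `downsample()` to the target
  resolution — 40 evenly spaced snapshots for the harvest conditions —
  emulating the sparse sampling of real observation campaigns.
* **Ensemble seeding.**  `make_ensemble()` derives realisation seeds from
  the master seed by a fixed counter hash (`derive_seeds()`), so any
  single realisation can be regenerated in isolation.

## Detrending

Rolling statistics presume an approximately stationary mean, so

* the spatial-mean series is detrended by removing its ordinary
  least-squares line on the driver (`detrend_linear()`), and
* the snapshot stack is detrended *uniformly* by subtracting each
  snapshot's own spatial mean from all of its sites
  (`detrend_spatial_mean()`).

The uniform spatial detrending requires no window size or bandwidth,
which is exactly why the per-snapshot spatial indicators are invariant to
the window-size choices probed in the sensitivity analysis.

## The indicators

Temporal, on the detrended spatial mean over *backwards* rolling windows
of `W_s` points ending at the current time (only past data informs each
value; entries before the first full window are masked):

| indicator  | definition |
|------------|------------|
| `variance` | sample variance, denominator `W_s − 1` |
| `skewness` | `m₃/m₂^{3/2}`, population moments |
| `ar1`      | OLS slope (with intercept) of `X_t` on `X_{t−1}` |
| `acf1`     | plug-in lag-1 autocorrelation of the window |

Spatially informed, on the spatio-temporal residuals:

* `spatial_variance`, `spatial_skewness` — per-snapshot site moments
  (variance unbiased, skewness population moments).  Permutation-invariant
  "multivariate" statistics.
* `spatial_correlation` — Moran's I with binary lag-1 rook weights
  (edge-sharing neighbours only).  Computed by neighbour-sum shifts, so
  the `N² × N²` weight matrix is never formed; periodic wrap-around by
  default to match the simulations, truncated weights for empirical
  rasters.  Moran's I is a true spatial statistic: permuting sites changes
  it.
* `eigen_max`, `eigen_fraction` — the largest eigenvalue of the unbiased
  windowed covariance matrix of the site series, and its share of the
  total variation (eigenvalue sum = trace).  The spectrum is computed
  from the `W_s × W_s` Gram matrix of the centred window vectors — the
  nonzero eigenvalues coincide with the direct `N² × N²` estimator's
  (validated against it on small lattices) at a tiny fraction of the
  cost, since at most `W_s − 1` eigenvalues are nonzero anyway.

Estimator conventions (denominators, biased vs unbiased ACF) follow the
common usage of the EWS literature and are stated in each function's
documentation; windows include the current point, and the alternative
conventions are documented switches where they exist.

## Trend strength and significance

An indicator's trend is Kendall's τ (tie-corrected τ_b) against the
driver — the bifurcation parameter for synthetic data, time or a spatial
index for empirical data.  Because τ is a rank statistic it is invariant
under any strictly increasing relabelling of the driver, so correlating
against the parameter and against time are equivalent when the parameter
drifts linearly.

Overlapping windows make successive indicator values strongly serially
dependent, which inflates the false-positive rate of the classical
Mann–Kendall trend test.  `modified_mann_kendall()` therefore multiplies
the tie-corrected score variance by the Hamed–Rao factor

    n/n_s* = 1 + 2/(n(n−1)(n−2)) · Σ_k (n−k)(n−k−1)(n−k−2)·ρ_s(k),

where `ρ_s(k)` are lag-`k` autocorrelations of the ranks of the
Sen-slope-detrended series.  Only lags whose autocorrelation exceeds the
two-sided 5% white-noise bound `1.96/√n` enter the sum (capped at `n/4`):
the unscreened sum is noise-dominated.  A factor below 1 is floored at 1,
a safeguard against variance deflation.  Two-sided test at `α = 0.05`
with continuity correction `Z = (S − sgn S)/√Var(S)`, `n ≥ 10` required.
Monte-Carlo calibration (part of the test suite) puts the empirical
type-I error on iid noise inside [3.5%, 6.5%] and shows the correction
strictly taming the inflation under trendless AR(1) dependence.

Each indicator also carries its *expected direction* under CSD
(`indicator_table()`); directions are reported alongside the signed τ,
never folded into the p-value, since disagreement with the expected
direction is itself a finding.

## Assessment protocol

Trend analysis is restricted to a driver interval that precedes the
tipping point.  The tipping location is itself estimated from the data
(`estimate_tipping()`): the largest single-step change of the
downsampled spatial-mean series, accepted when it exceeds 25% of the
series range.  The threshold formalises "the sudden shift visible in the
spatial mean" as the dominant discontinuity; it is parameter-light and
reproducible, and absence of a qualifying jump is a valid result, not an
error.  For the harvest conditions the default analysis interval is
`c ∈ [1, 2.55]`, inclusive on both ends, safely below the observed
tipping locations near 2.6.

`window_sensitivity()` sweeps the indicators over a grid of window sizes
expressed as percentages of the series length (`W_s = round(p·T)`,
floored at 3), computing one trend test per (indicator, window) cell;
window-free indicators are computed once and replicated, their τ exactly
constant across the grid.  The default grid is 9 evenly spaced
percentages over 25–50% — appropriate for a 40-snapshot series, where
smaller windows contain too few points for stable estimates.
`ensemble_summary()` aggregates repeated realisations into mean τ,
standard deviation of τ, and the percentage of realisations with
significant trends — a more robust basis for comparison than any single
realisation's p-value.

## What the generator does and does not emulate

The synthetic stacks share the key features of observational
spatio-temporal data: sparse, regular temporal sampling of a densely
evolving field; a monotone environmental driver; spatial correlation
induced by local coupling; and a genuine, contained transition.  They do
*not* emulate observation error, missing cells, irregular sampling,
spatially heterogeneous or correlated noise, non-square or non-periodic
domains, or coarse-grained measurements.  Conclusions from passing tests
therefore concern the indicators' behaviour under idealised conditions;
on real rasters the reader should expect the additional noise sources to
weaken trends before they invalidate the machinery.

## Problem sizes used in the automated checks

The test suite exercises the full harvest-scale conditions (100 × 100
lattice, ε = 0.001, 180,000 Euler steps per realisation) with a
10-realisation ensemble, and uses the small bistable model elsewhere;
Monte-Carlo calibrations use 2000 iid and 400 AR(1) replicates of length
100.  These sizes were chosen as the smallest at which the ensemble
statistics of interest are stable.

## Known limitations

* The asymptotic Mann–Kendall test is refused below `n = 10`; short
  subsets should use longer series or wider intervals rather than a
  small-sample exact test, which the package does not implement.
* The Hamed–Rao lag screening makes the corrected variance a
  discontinuous function of the data; near the screening boundary the
  p-value can jump.  This is inherent to the published procedure.
* Only additive, site-independent white noise is supported; the
  `state_floor` reflection is exact for the reflected Euler scheme but is
  a modelling choice, not part of the underlying SDE.
* `fold_point()` is a local two-variable Newton iteration: it needs a
  starting point on the correct branch, and a degenerate (non-fold)
  tangency will fail to converge rather than mislead.

## A worked miniature

```{r example, eval = FALSE}
cfg <- run_config(model = "bistable", model_args = list(lattice_n = 10L),
                  dt = 0.05, n_snapshots = 60,
                  subset_lower = 0, subset_upper = 0.35,
                  window_pcts = c(25, 37.5, 50),
                  n_realisations = 5, base_seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
res$tipping                      # ~0.39: just past the fold at 2/(3*sqrt(3))
window_free_table(res$summary)   # the compact indicator comparison
```

The same pipeline at the harvest scale (`model = "harvest"`, defaults)
reproduces the study conditions discussed above; see the README for how
`scripts/acceptance.R` re-derives the headline tipping location from
scratch.
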