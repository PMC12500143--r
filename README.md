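# ewsassess

Assessing and comparing early warning signals (EWS) of critical
transitions in spatially structured systems.

## What this package is for

Bistable systems under a slowly drifting condition — a biomass under
rising harvesting pressure, airways under increasing constricting force —
collapse abruptly when the drift carries them past a fold bifurcation.
Because the approach to the fold is accompanied by *critical slowing
down*, statistics of the observed fluctuations (variance,
autocorrelation, spatial correlation, covariance spectra) may trend
upward before the collapse and thereby act as early warnings.

For spatio-temporal data there are two competing families of indicators:
**temporal** EWS computed from the spatial mean of each snapshot, and
**spatially informed** EWS computed from the within-snapshot structure.
`ewsassess` is a laboratory for comparing them on equal terms.  It
provides, end to end:

1. **Simulation** — fast–slow stochastic lattice dynamical systems
   integrated with Euler–Maruyama: local reaction, nearest-neighbour
   diffusion (periodic discrete Laplacian), additive white noise, and a
   bifurcation parameter drifting linearly at rate ε.  Built-in models:
   the overharvesting model
   `f(v, c) = r·v·(1 − v/K) − c·v²/(v² + h₀²)` (fold at `c ≈ 2.604` for
   `r=1, K=10, h₀=1`) and the bistable normal form `−x³ + x + a` (fold at
   `2/(3√3)`).  Custom reactions plug in as R functions.
2. **Preprocessing** — spatial-mean reduction, linear detrending,
   uniform spatial-mean removal, data-driven tipping-point location, and
   pre-tipping subset selection.
3. **Indicators** — rolling variance / skewness / AR(1) / ACF(1) on the
   detrended spatial mean; per-snapshot spatial variance, spatial
   skewness, and Moran's I (lag-1 rook adjacency); the largest eigenvalue
   of the windowed site-covariance matrix and its share of total
   variation (via the Gram-matrix trick).
4. **Trend statistics** — Kendall's τ against the driver, Sen's slope,
   and the Hamed–Rao modified Mann–Kendall test, whose score variance is
   inflated by the significant rank autocorrelations of the detrended
   series to stay calibrated on the serially dependent traces that
   rolling windows produce.
5. **Assessment** — window-size sensitivity sweeps, replicate ensembles,
   and per-indicator summaries (mean τ, sd τ, % significant trends).

## A worked example

A five-realisation ensemble of the small bistable model, assessed over a
pre-tipping subset with three window sizes:

```r
library(ewsassess)
cfg <- run_config(model = "bistable", model_args = list(lattice_n = 10L),
                  dt = 0.05, n_snapshots = 60,
                  subset_lower = 0, subset_upper = 0.35,
                  window_pcts = c(25, 37.5, 50),
                  n_realisations = 5, base_seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
round(res$tipping, 4)
#> [1] 0.4373 0.4270 0.4373 0.4270 0.4270
window_free_table(res$summary)
#>             indicator mean_tau sd_tau pct_significant n_realisations p_value
#> 1 spatial_correlation   0.1494 0.0625               0              5      NA
#> 2    spatial_skewness   0.0538 0.1057               0              5      NA
#> 3    spatial_variance   0.6706 0.0527             100              5      NA
```

Reading the output: every realisation tips at `a ≈ 0.43` — just past the
fold of the frozen subsystem at `2/(3√3) ≈ 0.385`, the delay being the
slow-passage effect of a finite drift rate.  Spatial variance rises
towards the transition (mean τ ≈ 0.67, significant in 5/5 realisations),
while on this small, weakly coupled lattice spatial correlation and
skewness carry no usable trend — indicator performance is system
specific, which is the point of assessing before trusting.  Windowed
indicators appear in `res$summary` with one row per (indicator, window)
cell; a cell whose window leaves fewer than 10 pre-tipping points (here
the 50% window) is reported `NA` with the reason recorded in the
per-realisation grids.

The full-scale study conditions are the defaults of `harvest_model()`:
a 100×100 lattice, σ = 0.1, ε = 0.001, harvesting rate driven from 1 to
2.8 and downsampled to 40 snapshots, analysed on `c ∈ [1, 2.55]`.  One
realisation takes ~25 s:

```r
series <- simulate_tipping_data(harvest_model(), sim_config(seed = 7))
estimate_tipping(spatial_mean_series(series))
#> [1] 2.6155
```

## Package layout

| module | contents |
|---|---|
| `R/simulate.R` | model/config specs, equilibrium & fold solvers, Euler–Maruyama driver, downsampling, ensembles |
| `R/preprocess.R` | detrending, tipping location, subset selection |
| `R/ews_temporal.R` | rolling-window temporal indicators |
| `R/ews_spatial.R` | spatial/multivariate indicators |
| `R/trend_stats.R` | Kendall's τ, Sen's slope, modified Mann–Kendall |
| `R/assess.R` | sensitivity sweeps, ensemble summaries, plotting |
| `R/io.R` | CSV/YAML serialisation, run configuration, `run_pipeline()` |
| `src/em_integrate.cpp` | compiled integrator with its own deterministic RNG |

The methods vignette (`vignettes/ews-assessment.Rmd`) documents the
model, estimator conventions, numerical safeguards and design choices in
detail.
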