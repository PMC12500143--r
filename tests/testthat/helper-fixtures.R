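# Shared fixtures.  Expensive simulations are computed lazily and cached
# for the duration of the test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# a quick noisy bistable run shared by pipeline-level tests
quick_bistable <- function() {
  cached("quick_bistable", {
    simulate_tipping_data(bistable_model(lattice_n = 10L),
                          sim_config(dt = 0.05, seed = 42, n_snapshots = 60))
  })
}

# the full-scale harvest ensemble used by the acceptance-level checks
# (10 realisations of a 100x100 lattice; computed once)
harvest_ensemble <- function() {
  cached("harvest_ensemble", {
    make_ensemble(harvest_model(), sim_config(seed = 1, n_snapshots = 40),
                  n_realisations = 10, base_seed = 20260922)
  })
}

# random scalar series helper
rand_series <- function(n, seed = 1) {
  set.seed(seed)
  scalar_series(rnorm(n), seq_len(n), driver_kind = "time")
}

expect_all_equal <- function(x, tol = 1e-12) {
  expect_lt(max(x) - min(x), tol)
}
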