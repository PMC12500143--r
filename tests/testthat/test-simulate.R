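test_that("harvest reaction term evaluates the overharvesting drift", {
  # both terms vanish at v = 0; logistic term vanishes at carrying capacity
  expect_identical(harvest_reaction(0, 0), 0)
  expect_identical(harvest_reaction(0, 3.7), 0)
  expect_identical(harvest_reaction(10, 0), 0)
  # direct evaluation: 1 * (1 - 0.1) - 1/(1 + 1)
  expect_equal(harvest_reaction(1, 1), 0.4)
  expect_equal(harvest_reaction(c(0, 1, 10), 1),
               c(0, 0.4, harvest_reaction(10, 1)))
})

test_that("fold of the homogeneous harvest subsystem sits near c = 2.604", {
  fp <- fold_point(harvest_model(), v0 = 4, p0 = 2.5)
  expect_equal(fp$param, 2.604, tolerance = 1e-3)
  # fold conditions hold: f = 0 and df/dv = 0
  expect_lt(abs(harvest_reaction(fp$state, fp$param)), 1e-8)
  eps <- 1e-6
  dfdv <- (harvest_reaction(fp$state + eps, fp$param) -
             harvest_reaction(fp$state - eps, fp$param)) / (2 * eps)
  expect_lt(abs(dfdv), 1e-5)
})

test_that("bistable fixture fold is recovered at the analytic location", {
  fp <- fold_point(bistable_model(), v0 = -0.5, p0 = 0.3)
  expect_equal(fp$param, 2 / (3 * sqrt(3)), tolerance = 1e-6)
  expect_equal(fp$state, -1 / sqrt(3), tolerance = 1e-6)
})

test_that("discrete Laplacian implements the periodic 5-point stencil", {
  # constant field maps to zero
  expect_equal(discrete_laplacian(matrix(3.2, 5, 5)), matrix(0, 5, 5))
  # unit impulse on a 4x4 periodic lattice: -4 at the site, +1 at the four
  # rook neighbours, 0 elsewhere
  x <- matrix(0, 4, 4)
  x[2, 3] <- 1
  expected <- matrix(0, 4, 4)
  expected[2, 3] <- -4
  expected[1, 3] <- expected[3, 3] <- expected[2, 2] <- expected[2, 4] <- 1
  expect_equal(discrete_laplacian(x), expected)
  # conservation: output sums to zero on random fields
  set.seed(5)
  for (n in c(2, 3, 7)) {
    f <- matrix(rnorm(n * n), n, n)
    expect_lt(abs(sum(discrete_laplacian(f))), 1e-10)
  }
  expect_error(discrete_laplacian(matrix(0, 2, 3)), "square")
})

test_that("initial condition is the homogeneous equilibrium of the fast subsystem", {
  m <- harvest_model()
  v0 <- find_equilibrium(m)
  expect_lt(abs(harvest_reaction(v0, 1)), 1e-10)
  expect_gt(v0, 8)   # upper branch, near carrying capacity
  b <- bistable_model()
  x0 <- find_equilibrium(b)
  expect_lt(abs(bistable_reaction(x0, 0)), 1e-10)
  expect_equal(x0, -1, tolerance = 1e-9)
})

test_that("zero-noise frozen-driver runs stay at equilibrium", {
  # epsilon cannot be 0 by construction; make the driver change negligible
  m <- model_spec("bistable", coupling = 0.1, noise_sigma = 0,
                  param_name = "a", param_start = 0, param_end = 1e-8,
                  epsilon = 1e-12, lattice_n = 4L, init_guess = -1)
  cfg <- sim_config(dt = 0.05, seed = 1, n_snapshots = 2, record_every = 1L)
  raw <- simulate_fast_slow(m, cfg)
  x0 <- raw$data[, , 1]
  drift <- apply(raw$data, 3, function(s) max(abs(s - x0)))
  n_steps <- dim(raw$data)[3] - 1
  expect_lt(max(drift), 1e-10 * n_steps)
})

test_that("sigma = 0 lattice dynamics reduce to the scalar fast-slow ODE", {
  m <- bistable_model(lattice_n = 5L, noise_sigma = 0)
  cfg <- sim_config(dt = 0.05, seed = 1, n_snapshots = 10, record_every = 1L)
  raw <- simulate_fast_slow(m, cfg)
  # homogeneous lattice: every snapshot is spatially constant
  expect_lt(max(apply(raw$data, 3, function(s) diff(range(s)))), 1e-12)
  # independent scalar Euler oracle of the same reaction
  n_steps <- ceiling((m$param_end - m$param_start) / m$epsilon / cfg$dt)
  v <- find_equilibrium(m)
  p <- m$param_start
  traj <- numeric(n_steps + 1)
  traj[1] <- v
  for (s in seq_len(n_steps)) {
    v <- v + bistable_reaction(v, p) * cfg$dt
    p <- m$param_start + m$epsilon * (s * cfg$dt)
    traj[s + 1] <- v
  }
  expect_lt(max(abs(spatial_mean_series(raw)$values - traj)), 1e-8)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- bistable_model(lattice_n = 8L)
  cfg <- sim_config(dt = 0.05, seed = 99, n_snapshots = 20)
  a <- simulate_tipping_data(m, cfg)
  b <- simulate_tipping_data(m, cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$driver, b$driver)
  c2 <- simulate_tipping_data(m, sim_config(dt = 0.05, seed = 100,
                                            n_snapshots = 20))
  expect_false(identical(a$data, c2$data))
})

test_that("unstable dt is rejected before integration", {
  m <- bistable_model(coupling = 10)
  expect_error(simulate_fast_slow(m, sim_config(dt = 0.05, seed = 1)),
               "stability")
})

test_that("SPDE scaling maps onto an equivalent SLDS integration", {
  # D/h^2 coupling and sigma/h noise: an SPDE model on spacing h must equal
  # the SLDS model with those effective coefficients, seed for seed
  h <- 0.5
  spde <- model_spec("bistable", coupling = 0.1, noise_sigma = 0.04,
                     param_name = "a", param_start = 0, param_end = 0.5,
                     epsilon = 0.01, lattice_n = 6L, init_guess = -1,
                     scaling = "spde", h = h)
  slds <- model_spec("bistable", coupling = 0.1 / h^2,
                     noise_sigma = 0.04 / h, param_name = "a",
                     param_start = 0, param_end = 0.5, epsilon = 0.01,
                     lattice_n = 6L, init_guess = -1)
  cfg <- sim_config(dt = 0.05, seed = 3, n_snapshots = 10)
  expect_identical(simulate_tipping_data(spde, cfg)$data,
                   simulate_tipping_data(slds, cfg)$data)
})

test_that("custom R-function reactions integrate through the plug-in path", {
  custom <- model_spec(function(x, a) -x^3 + x + a, coupling = 0.1,
                       noise_sigma = 0, param_name = "a", param_start = 0,
                       param_end = 0.5, epsilon = 0.01, lattice_n = 4L,
                       init_guess = -1)
  builtin <- model_spec("bistable", coupling = 0.1, noise_sigma = 0,
                        param_name = "a", param_start = 0, param_end = 0.5,
                        epsilon = 0.01, lattice_n = 4L, init_guess = -1)
  cfg <- sim_config(dt = 0.05, seed = 1, n_snapshots = 10)
  # with sigma = 0 both paths are deterministic and must agree numerically
  expect_equal(simulate_tipping_data(custom, cfg)$data,
               simulate_tipping_data(builtin, cfg)$data, tolerance = 1e-12)
})

test_that("downsampling keeps evenly spaced snapshots including the last", {
  s <- quick_bistable()
  T_len <- dim(s$data)[3]
  expect_identical(downsample(s, T_len)$data, s$data)   # identity
  d <- downsample(s, 7)
  expect_identical(dim(d$data)[3], 7L)
  expect_identical(d$data[, , 7], s$data[, , T_len])    # final retained
  expect_identical(d$driver[1], s$driver[1])            # first retained
  expect_all_equal(diff(d$driver), tol = diff(range(s$driver)) / 10)
  expect_error(downsample(s, 1), ">= 2")
  expect_error(downsample(s, T_len + 1), "exceeds")
})

test_that("ensembles are reproducible and realisation-wise deterministic", {
  m <- bistable_model(lattice_n = 6L)
  cfg <- sim_config(dt = 0.05, seed = 1, n_snapshots = 10)
  e1 <- make_ensemble(m, cfg, 3, base_seed = 7)
  e2 <- make_ensemble(m, cfg, 3, base_seed = 7)
  for (k in 1:3) expect_identical(e1[[k]]$data, e2[[k]]$data)
  # realisations differ from each other
  expect_false(identical(e1[[1]]$data, e1[[2]]$data))
  # a single realisation equals a direct run with the derived seed
  seeds <- attr(e1, "seeds")
  cfg1 <- cfg
  cfg1$seed <- seeds[2]
  expect_identical(simulate_tipping_data(m, cfg1)$data, e1[[2]]$data)
  # different base seeds decorrelate
  e3 <- make_ensemble(m, cfg, 1, base_seed = 8)
  expect_false(identical(e3[[1]]$data, e1[[1]]$data))
})
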