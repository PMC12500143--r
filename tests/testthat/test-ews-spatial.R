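test_that("spatial variance and skewness are permutation-invariant moments", {
  expect_equal(spatial_variance(matrix(1:4, 2, 2)), 5 / 3)
  expect_equal(spatial_variance(matrix(7, 4, 4)), 0)
  # skewness of [0,0,0,1]: m2 = 3/16, m3 = 9/64 -> 2/sqrt(3)
  expect_equal(spatial_skewness(matrix(c(0, 0, 0, 1), 2, 2)), 2 / sqrt(3),
               tolerance = 1e-6)
  expect_equal(spatial_skewness(matrix(c(-2, 0, 0, 2), 2, 2)), 0)
  expect_warning(v <- spatial_skewness(matrix(1, 3, 3)), "constant")
  expect_true(is.na(v))
  # permuting the sites leaves both unchanged
  set.seed(4)
  snap <- matrix(rnorm(36), 6, 6)
  perm <- matrix(sample(as.vector(snap)), 6, 6)
  expect_equal(spatial_variance(perm), spatial_variance(snap))
  expect_equal(spatial_skewness(perm), spatial_skewness(snap))
})

test_that("Moran's I matches the checkerboard and the dense-matrix oracle", {
  # periodic rook checkerboard: every neighbour has the opposite sign
  cb <- outer(1:4, 1:4, function(i, j) (-1)^(i + j))
  expect_equal(morans_i(cb, "periodic"), -1)
  expect_warning(v <- morans_i(matrix(2, 4, 4)), "constant")
  expect_true(is.na(v))
  # Moran's I is NOT permutation-invariant: sorting the checkerboard
  # rearranges the adjacency relations
  sorted <- matrix(sort(as.vector(cb)), 4, 4)
  expect_false(isTRUE(all.equal(morans_i(sorted), morans_i(cb))))
  # dense weight-matrix oracles on random lattices.  ape row-normalises its
  # weights, which coincides with binary weights only when all row sums are
  # equal, i.e. under periodic boundaries; the truncated rule is checked
  # against a direct dense-formula evaluation instead.
  skip_if_not_installed("ape")
  set.seed(9)
  for (n in c(3, 6)) {
    snap <- matrix(rnorm(n * n), n, n)
    ref <- ape::Moran.I(as.vector(snap), rook_weights(n, "periodic"),
                        scaled = FALSE)$observed
    expect_equal(morans_i(snap, "periodic"), ref, tolerance = 1e-10)
    # truncated: I = (n2/S0) * sum_ij w_ij d_i d_j / sum_i d_i^2
    W <- rook_weights(n, "truncate")
    d <- as.vector(snap) - mean(snap)
    ref2 <- (n * n / sum(W)) * as.numeric(t(d) %*% W %*% d) / sum(d^2)
    expect_equal(morans_i(snap, "truncate"), ref2, tolerance = 1e-10)
  }
})

test_that("rook weights are symmetric, binary, zero-diagonal, degree 4", {
  W <- rook_weights(5, "periodic")
  expect_identical(W, t(W))
  expect_true(all(W %in% c(0, 1)))
  expect_true(all(diag(W) == 0))
  expect_true(all(rowSums(W) == 4))
  Wt <- rook_weights(5, "truncate")
  expect_true(all(rowSums(Wt) %in% 2:4))
  expect_equal(sum(Wt), 2 * (2 * 5 * 4))
})

test_that("Moran's I null expectation and diffusion response", {
  # iid snapshots: mean I over replicates near -1/(n-1) ~ 0
  set.seed(17)
  vals <- vapply(1:40, function(i) morans_i(matrix(rnorm(2500), 50, 50)),
                 numeric(1))
  expect_lt(abs(mean(vals)), 0.01)
  # smoothing a random field by diffusion raises I in almost every trial
  set.seed(18)
  hits <- vapply(1:40, function(i) {
    x <- matrix(rnorm(400), 20, 20)
    xs <- x + 0.2 * discrete_laplacian(x)    # one diffusive smoothing step
    morans_i(xs) > morans_i(x)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Gram-trick covariance spectrum equals the direct estimator", {
  set.seed(6)
  N <- 4; n_win <- 6
  snaps <- array(rnorm(N * N * n_win), dim = c(N, N, n_win))
  series <- lattice_series(snaps, 1:n_win, driver_kind = "time")
  ews <- eigen_ews(series, n_win)
  # direct N^2 x N^2 covariance oracle
  X <- t(matrix(snaps, N * N, n_win))       # n x N^2, rows = snapshots
  S <- stats::cov(X)                        # unbiased, denominator n-1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ews$lambda_max$values[n_win], max(ev), tolerance = 1e-9)
  expect_equal(ews$lambda_frac$values[n_win], max(ev) / sum(ev),
               tolerance = 1e-9)
  # eigenvalue sum equals the covariance trace (total variation)
  expect_equal(ews$lambda_max$values[n_win] / ews$lambda_frac$values[n_win],
               sum(diag(S)), tolerance = 1e-8)
})

test_that("eigen indicators: masking, degenerate windows, invariances", {
  set.seed(7)
  N <- 5; T_len <- 12
  snaps <- array(rnorm(N * N * T_len), dim = c(N, N, T_len))
  series <- lattice_series(snaps, 1:T_len, driver_kind = "time")
  ews <- eigen_ews(series, 4)
  expect_identical(ews$lambda_max$valid, c(rep(FALSE, 3), rep(TRUE, 9)))
  # fraction in (0, 1]
  fr <- ews$lambda_frac$values[4:T_len]
  expect_true(all(fr > 0 & fr <= 1))
  # at most n-1 nonzero eigenvalues => with n = 2 the fraction is 1
  ews2 <- eigen_ews(series, 2)
  expect_equal(ews2$lambda_frac$values[2:T_len], rep(1, T_len - 1),
               tolerance = 1e-9)
  # identical snapshots: lambda_max = 0, fraction masked
  const <- lattice_series(array(1, c(3, 3, 4)), 1:4, driver_kind = "time")
  expect_warning(ec <- eigen_ews(const, 3), "identical")
  expect_equal(ec$lambda_max$values[3:4], c(0, 0))
  expect_true(all(is.na(ec$lambda_frac$values)))
  # site permutation applied to every snapshot leaves the spectrum alone
  perm <- sample(N * N)
  X <- matrix(snaps, N * N, T_len)[perm, ]
  pseries <- lattice_series(array(X, c(N, N, T_len)), 1:T_len,
                            driver_kind = "time")
  pews <- eigen_ews(pseries, 4)
  expect_equal(pews$lambda_max$values, ews$lambda_max$values,
               tolerance = 1e-9)
  # total variance conservation on raw vs spatially detrended input
  resid <- detrend_spatial_mean(series)
  rews <- eigen_ews(resid, 4)
  t <- 8
  Z <- matrix(resid$data, N * N, T_len)[, 5:8]
  expect_equal(rews$lambda_max$values[t] / rews$lambda_frac$values[t],
               sum(apply(Z, 1, stats::var)), tolerance = 1e-8)
})
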