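# Spatially informed early warning indicators.  Spatial variance and
# skewness are per-snapshot, permutation-invariant ("multivariate")
# statistics; Moran's I depends on the adjacency structure and is a true
# spatial statistic; the covariance-eigenvalue indicators are multivariate
# and window-based.

as_snapshot <- function(snapshot) {
  if (!is.matrix(snapshot) || nrow(snapshot) != ncol(snapshot))
    stop("`snapshot` must be a square matrix", call. = FALSE)
  snapshot
}

#' Spatial variance of a snapshot
#'
#' Sample variance over all `N^2` sites (denominator `N^2 - 1`).  Invariant
#' under permutations of the sites.
#'
#' @param snapshot numeric `N x N` matrix.
#' @return Scalar variance.
#' @export
spatial_variance <- function(snapshot) {
  stats::var(as.vector(as_snapshot(snapshot)))
}

#' Spatial skewness of a snapshot
#'
#' Central-moment skewness `m3 / m2^(3/2)` over all sites (population
#' denominators).  Invariant under permutations of the sites; constant
#' snapshots are undefined and return `NA` with a warning.
#'
#' @param snapshot numeric `N x N` matrix.
#' @return Scalar skewness, or `NA` for a constant snapshot.
#' @export
spatial_skewness <- function(snapshot) {
  x <- as.vector(as_snapshot(snapshot))
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) {
    warning("spatial skewness undefined on a constant snapshot; masking",
            call. = FALSE)
    return(NA_real_)
  }
  mean(d^3) / m2^1.5
}

#' Rook adjacency weights for an `N x N` lattice
#'
#' Binary weight matrix over the `N^2` sites (column-major order) with
#' `w[i, j] = 1` exactly when sites `i` and `j` share an edge (lag-1 rook
#' neighbours; vertex-sharing diagonal neighbours are not adjacent).  Under
#' periodic boundaries every site has degree 4; the truncated rule drops
#' wrap-around edges, for empirical rasters.  Intended for small lattices
#' (the matrix is dense); [morans_i()] itself never forms it.
#'
#' @param n_side lattice side `N`.
#' @param boundary `"periodic"` or `"truncate"`.
#' @return Symmetric `N^2 x N^2` 0/1 matrix with zero diagonal.
#' @export
rook_weights <- function(n_side, boundary = c("periodic", "truncate")) {
  boundary <- match.arg(boundary)
  N <- as.integer(n_side)
  n <- N * N
  W <- matrix(0, n, n)
  id <- function(i, j) i + N * (j - 1L)
  for (j in seq_len(N)) {
    for (i in seq_len(N)) {
      me <- id(i, j)
      nb <- list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
      for (p in nb) {
        ii <- p[1L]; jj <- p[2L]
        if (boundary == "periodic") {
          ii <- ((ii - 1L) %% N) + 1L
          jj <- ((jj - 1L) %% N) + 1L
        } else if (ii < 1L || ii > N || jj < 1L || jj > N) next
        W[me, id(ii, jj)] <- 1
      }
    }
  }
  W
}

# sum over the four rook neighbours of every site, by matrix shifts
rook_neighbour_sum <- function(x, boundary) {
  n <- nrow(x)
  if (boundary == "periodic") {
    up <- c(n, seq_len(n - 1L))
    dn <- c(seq_len(n - 1L) + 1L, 1L)
    x[up, ] + x[dn, ] + x[, up] + x[, dn]
  } else {
    s <- matrix(0, n, n)
    s[-1L, ] <- s[-1L, ] + x[-n, ]
    s[-n, ] <- s[-n, ] + x[-1L, ]
    s[, -1L] <- s[, -1L] + x[, -n]
    s[, -n] <- s[, -n] + x[, -1L]
    s
  }
}

#' Moran's I spatial autocorrelation of a snapshot
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - m)(x_j - m) / sum_i (x_i - m)^2` with
#' `n = N^2` sites, lag-1 rook weights `w` ([rook_weights()]) and
#' `S0 = sum_ij w_ij`.  Computed by neighbour-sum shifts, so large lattices
#' never materialise the weight matrix.  Moran's I is *not* invariant under
#' site permutations: it measures genuinely spatial structure, and rises as
#' diffusive coupling correlates neighbouring sites ahead of a transition.
#'
#' @param snapshot numeric `N x N` matrix.
#' @param boundary `"periodic"` (matching the simulations) or `"truncate"`
#'   (for empirical rasters).
#' @return Scalar Moran's I, or `NA` for a constant snapshot (warning).
#' @export
morans_i <- function(snapshot, boundary = c("periodic", "truncate")) {
  boundary <- match.arg(boundary)
  x <- as_snapshot(snapshot)
  n_side <- nrow(x)
  n <- n_side * n_side
  d <- x - mean(x)
  ss <- sum(d * d)
  if (ss == 0) {
    warning("Moran's I undefined on a constant snapshot; masking",
            call. = FALSE)
    return(NA_real_)
  }
  S0 <- if (boundary == "periodic") 4 * n else 2 * (2 * n_side * (n_side - 1))
  num <- sum(d * rook_neighbour_sum(d, boundary))
  (n / S0) * num / ss
}

#' Covariance-matrix eigenvalue indicators
#'
#' Over a backwards rolling window of `n = W_s` snapshots, the `N^2 x N^2`
#' covariance matrix of the site series is estimated with the unbiased
#' estimator
#' `S_jk = sum_i (X_ij - Xbar_j)(X_ik - Xbar_k) / (n - 1)`;
#' its largest eigenvalue, and the share of the total variation (eigenvalue
#' sum = trace) that it accounts for, both tend to grow as the dominant
#' mode destabilises on approach to a transition.
#'
#' The nonzero spectrum is obtained from the `n x n` Gram matrix of the
#' centred window vectors — identical to the direct covariance spectrum but
#' tractable when `n << N^2`.  Input snapshots should already be spatially
#' detrended ([detrend_spatial_mean()]).
#'
#' @param series a [lattice_series()] (spatio-temporal residuals).
#' @param W_s window length in snapshots, `2 <= W_s <= T`.
#' @return A list with elements `lambda_max` and `lambda_frac`, each an
#'   [ews_trace()] masked for `t < W_s`.  A window of identical snapshots
#'   yields `lambda_max = 0` and a masked fraction (0/0), with a warning.
#' @export
eigen_ews <- function(series, W_s) {
  stopifnot(inherits(series, "lattice_series"))
  d <- dim(series$data)
  T_len <- d[3L]
  W_s <- as.integer(W_s)
  if (W_s < 2L || W_s > T_len)
    stop("window length ", W_s, " outside the admissible range [2, ", T_len,
         "]", call. = FALSE)
  X <- matrix(series$data, d[1L] * d[2L], T_len)
  lmax <- lfrac <- rep(NA_real_, T_len)
  warned <- FALSE
  for (t in W_s:T_len) {
    Z <- X[, (t - W_s + 1L):t, drop = FALSE]
    Z <- Z - rowMeans(Z)
    G <- crossprod(Z) / (W_s - 1)          # n x n Gram matrix
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    ev[ev < 0] <- 0                        # clip tiny negative round-off
    tot <- sum(ev)
    lmax[t] <- ev[1L]
    if (tot > 0) {
      lfrac[t] <- ev[1L] / tot
    } else if (!warned) {
      warning("eigen_ews: window of identical snapshots; ",
              "eigenvalue fraction masked", call. = FALSE)
      warned <- TRUE
    }
  }
  list(lambda_max = ews_trace(lmax, series$driver, "eigen_max", W_s,
                              series$driver_kind),
       lambda_frac = ews_trace(lfrac, series$driver, "eigen_fraction", W_s,
                               series$driver_kind))
}
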