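#' Specify a fast-slow stochastic lattice model
#'
#' A model couples a local reaction term on every site of an `N x N` lattice
#' with nearest-neighbour diffusion (discrete Laplacian), additive white
#' noise, and a bifurcation parameter that drifts linearly in time at rate
#' `epsilon` (the fast-slow timescale separation, `0 < epsilon << 1`).
#'
#' `reaction` is either the name of a built-in term (`"harvest"` or
#' `"bistable"`, integrated in compiled code) or an R function
#' `f(state, param)` vectorised over `state`, integrated by a pure-R path
#' suitable for small lattices.
#'
#' Two noise/coupling scaling conventions are supported.  An intrinsically
#' discrete lattice system (`scaling = "slds"`) uses `coupling` and
#' `noise_sigma` as given.  A discretised stochastic reaction-diffusion
#' equation (`scaling = "spde"`) on a grid of spacing `h` uses effective
#' coupling `coupling / h^2` and per-site noise `noise_sigma / h`, so that
#' the same continuum fields are approximated on different grids.
#'
#' @param reaction built-in name or function, see Details.
#' @param coupling diffusion coefficient `D` (per unit time).
#' @param noise_sigma standard deviation scale `sigma >= 0` of the white
#'   noise increments.
#' @param param_name driver label, e.g. `"c"` (harvesting rate).
#' @param param_start,param_end driver range; the range should extend past
#'   the fold so the transition is always present in the data.
#' @param epsilon timescale separation; the driver obeys
#'   `d(param)/dt = epsilon`.
#' @param lattice_n lattice side `N >= 2`.
#' @param init_guess starting point for the Newton solve of the initial
#'   homogeneous equilibrium.
#' @param scaling `"slds"` or `"spde"`, see Details.
#' @param h grid spacing (used by the `"spde"` scaling; the Laplacian
#'   stencil itself always uses unit spacing).
#' @param reaction_pars numeric parameters of a built-in reaction
#'   (`"harvest"`: `r`, `K`, `h0`).
#' @param state_floor reflecting lower barrier on the state (default
#'   `-Inf`, i.e. none).  A floor of 0 enforces non-negativity for models
#'   whose state is a physical density; reflection keeps the noise
#'   statistics intact when the barrier is far from the attracting branch.
#' @return An object of class `model_spec`.
#' @seealso [harvest_model()], [bistable_model()], [simulate_fast_slow()]
#' @export
model_spec <- function(reaction, coupling, noise_sigma, param_name,
                       param_start, param_end, epsilon, lattice_n,
                       init_guess, scaling = c("slds", "spde"), h = 1,
                       reaction_pars = numeric(), state_floor = -Inf) {
  scaling <- match.arg(scaling)
  if (!(is.function(reaction) ||
        (is.character(reaction) && reaction %in% c("harvest", "bistable"))))
    stop("`reaction` must be a function or one of \"harvest\", \"bistable\"",
         call. = FALSE)
  if (!(epsilon > 0 && epsilon < 1))
    stop("`epsilon` must satisfy 0 < epsilon < 1", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (lattice_n < 2) stop("`lattice_n` must be >= 2", call. = FALSE)
  if (param_end <= param_start)
    stop("`param_end` must exceed `param_start`", call. = FALSE)
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  structure(list(reaction = reaction, coupling = coupling,
                 noise_sigma = noise_sigma, param_name = param_name,
                 param_start = param_start, param_end = param_end,
                 epsilon = epsilon, lattice_n = as.integer(lattice_n),
                 init_guess = init_guess, scaling = scaling, h = h,
                 reaction_pars = reaction_pars, state_floor = state_floor),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  nm <- if (is.character(x$reaction)) x$reaction else "<custom>"
  cat("<model_spec> reaction ", nm, " on ", x$lattice_n, "x", x$lattice_n,
      " lattice (", x$scaling, ")\n", sep = "")
  cat("  ", x$param_name, ": ", x$param_start, " -> ", x$param_end,
      " at rate epsilon = ", x$epsilon, "\n", sep = "")
  cat("  D = ", x$coupling, ", sigma = ", x$noise_sigma, "\n", sep = "")
  invisible(x)
}

#' Logistic-growth model with Hill-type harvesting
#'
#' The classic overexploitation model with alternative stable states:
#' `f(v, c) = r*v*(1 - v/K) - c*v^2/(v^2 + h0^2)`, spatially extended on
#' a lattice with diffusive coupling.  With the default parameters
#' (`r=1`, `K=10`, `h0=1`) the homogeneous fast subsystem has a fold
#' at a harvesting rate of `c ~ 2.604`, where the abundant branch collapses
#' to the overexploited state.  Biomass is a density, so the integration
#' reflects the state at 0: with additive noise the region `v < 0` is
#' dynamically unstable (the logistic term accelerates the escape), and a
#' lattice held on the overexploited branch past the fold would otherwise
#' diverge.  The barrier sits several stationary standard deviations below
#' the overexploited branch and has no measurable effect before tipping.
#'
#' @param lattice_n lattice side, default 100.
#' @param noise_sigma white-noise scale, default 0.1.
#' @param epsilon driver drift rate, default 0.001.
#' @param param_start,param_end harvesting-rate range, default 1 to 2.8
#'   (past the fold).
#' @param coupling diffusion coefficient, default 0.1.
#' @param r,K,h0 reaction parameters: intrinsic growth rate, carrying
#'   capacity, half-saturation constant.
#' @return A `model_spec`.
#' @export
harvest_model <- function(lattice_n = 100L, noise_sigma = 0.1,
                          epsilon = 0.001, param_start = 1, param_end = 2.8,
                          coupling = 0.1, r = 1, K = 10, h0 = 1) {
  model_spec(reaction = "harvest", coupling = coupling,
             noise_sigma = noise_sigma, param_name = "c",
             param_start = param_start, param_end = param_end,
             epsilon = epsilon, lattice_n = lattice_n, init_guess = K,
             reaction_pars = c(r = r, K = K, h0 = h0), state_floor = 0)
}

#' Bistable cubic normal-form model
#'
#' The generic fold normal form `f(x, a) = -x^3 + x + a` on a lattice.  The
#' lower stable branch (near `x = -1` at `a = 0`) folds at
#' `a = 2 / (3 sqrt(3)) ~ 0.3849`; driving `a` upwards through the fold
#' tips the system to the upper branch.  Small and fast, it is the test
#' model of choice for exercising the pipeline.
#'
#' @param lattice_n lattice side, default 20.
#' @param noise_sigma white-noise scale, default 0.05.
#' @param epsilon driver drift rate, default 0.005.
#' @param param_start,param_end driver range, default 0 to 0.6 (past the
#'   fold at ~0.385).
#' @param coupling diffusion coefficient, default 0.1.
#' @return A `model_spec`.
#' @export
bistable_model <- function(lattice_n = 20L, noise_sigma = 0.05,
                           epsilon = 0.005, param_start = 0,
                           param_end = 0.6, coupling = 0.1) {
  model_spec(reaction = "bistable", coupling = coupling,
             noise_sigma = noise_sigma, param_name = "a",
             param_start = param_start, param_end = param_end,
             epsilon = epsilon, lattice_n = lattice_n, init_guess = -1)
}

#' Harvesting reaction term
#'
#' Drift rate of the local biomass: logistic growth minus a saturating
#' (Hill) harvesting loss, `r*v*(1 - v/K) - c*v^2/(v^2 + h0^2)`.
#'
#' @param v biomass value (vectorised).
#' @param c harvesting rate.
#' @param r,K,h0 growth rate, carrying capacity, half-saturation constant.
#' @return Drift rate(s), same shape as `v`.
#' @export
harvest_reaction <- function(v, c, r = 1, K = 10, h0 = 1) {
  r * v * (1 - v / K) - c * v^2 / (v^2 + h0^2)
}

#' Bistable cubic reaction term
#'
#' @param x state value (vectorised).
#' @param a driver value.
#' @return `-x^3 + x + a`.
#' @export
bistable_reaction <- function(x, a) -x^3 + x + a

# resolve a model's reaction to an R function f(state, param)
reaction_fn <- function(model) {
  if (is.function(model$reaction)) return(model$reaction)
  switch(model$reaction,
         harvest = function(v, p) {
           pr <- model$reaction_pars
           harvest_reaction(v, p, r = pr[["r"]], K = pr[["K"]],
                            h0 = pr[["h0"]])
         },
         bistable = function(x, p) bistable_reaction(x, p))
}

# effective (coupling, sigma) after applying the scaling convention
effective_coefs <- function(model) {
  if (model$scaling == "spde")
    list(D = model$coupling / model$h^2, sigma = model$noise_sigma / model$h)
  else
    list(D = model$coupling, sigma = model$noise_sigma)
}

#' Integration settings
#'
#' @param dt Euler-Maruyama step, default 0.01.  Stability of the diffusive
#'   stencil requires `dt <= h^2 / (4 D)` for unit lattice spacing; this is
#'   enforced when a simulation is launched.
#' @param seed non-negative integer RNG seed.
#' @param n_snapshots snapshots retained after downsampling (`>= 2`).
#' @param boundary boundary rule; only `"periodic"` is supported for
#'   simulation.
#' @param record_every record the raw trajectory every this many steps
#'   (`NULL`: every step when feasible, otherwise about ten times
#'   `n_snapshots` frames).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, seed = 1L, n_snapshots = 40L,
                       boundary = "periodic", record_every = NULL) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (n_snapshots < 2) stop("`n_snapshots` must be >= 2", call. = FALSE)
  if (!identical(boundary, "periodic"))
    stop("only periodic boundaries are supported for simulation",
         call. = FALSE)
  if (length(seed) != 1L || is.na(seed) || seed < 0 || seed != round(seed))
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  structure(list(dt = dt, seed = as.numeric(seed),
                 n_snapshots = as.integer(n_snapshots), boundary = boundary,
                 record_every = record_every),
            class = "sim_config")
}

#' Periodic 5-point discrete Laplacian
#'
#' `(Lap x)_{ij} = x_{i+1,j} + x_{i-1,j} + x_{i,j+1} + x_{i,j-1} - 4 x_{ij}`
#' with indices wrapped modulo `N`.  On periodic boundaries the stencil is
#' conservative: its output sums to zero.
#'
#' @param field numeric `N x N` matrix.
#' @param boundary only `"periodic"`.
#' @return Matrix of the same dimension.
#' @export
discrete_laplacian <- function(field, boundary = "periodic") {
  if (!is.matrix(field) || nrow(field) != ncol(field))
    stop("`field` must be a square matrix", call. = FALSE)
  if (!identical(boundary, "periodic"))
    stop("only periodic boundaries are supported", call. = FALSE)
  n <- nrow(field)
  up <- c(n, seq_len(n - 1L))
  dn <- c(seq_len(n - 1L) + 1L, 1L)
  field[up, ] + field[dn, ] + field[, up] + field[, dn] - 4 * field
}

#' Homogeneous equilibrium of the fast subsystem
#'
#' Newton iteration on `f(v, p) = 0` from `init_guess`, with a numerical
#' derivative.  Used to start simulations from the unperturbed homogeneous
#' equilibrium at `param_start`.
#'
#' @param model a `model_spec`.
#' @param param driver value at which to solve (default `param_start`).
#' @param tol convergence tolerance on `|f|` and the Newton step.
#' @param max_iter iteration cap.
#' @return The equilibrium state value (scalar).
#' @export
find_equilibrium <- function(model, param = model$param_start, tol = 1e-12,
                             max_iter = 200L) {
  f <- reaction_fn(model)
  v <- model$init_guess
  for (it in seq_len(max_iter)) {
    fv <- f(v, param)
    if (!is.finite(fv))
      stop("equilibrium solve diverged (non-finite reaction value)",
           call. = FALSE)
    eps <- max(abs(v), 1) * 1e-7
    dfv <- (f(v + eps, param) - f(v - eps, param)) / (2 * eps)
    if (!is.finite(dfv) || abs(dfv) < .Machine$double.xmin)
      stop("equilibrium solve stalled: zero derivative at v = ", v,
           call. = FALSE)
    step <- fv / dfv
    v <- v - step
    if (abs(fv) < tol && abs(step) < tol) return(v)
  }
  if (abs(f(v, param)) < 1e-8) return(v)
  stop("no equilibrium found from init_guess = ", model$init_guess,
       " at ", model$param_name, " = ", param,
       ": Newton did not converge", call. = FALSE)
}

#' Locate the fold of the homogeneous fast subsystem
#'
#' Solves the fold (saddle-node) conditions `f(v, p) = 0` and
#' `df/dv(v, p) = 0` by a two-variable Newton iteration with numerical
#' derivatives.  For the harvesting model with default parameters the fold
#' sits at `c ~ 2.604`; for the bistable normal form at
#' `a = 2 / (3 sqrt(3))`.
#'
#' @param model a `model_spec`.
#' @param v0,p0 starting point; defaults bracket the model's driver range.
#' @param tol residual tolerance.
#' @return Named list with elements `param` (fold driver value) and `state`
#'   (state value at the fold).
#' @export
fold_point <- function(model, v0 = NULL, p0 = NULL, tol = 1e-10) {
  f <- reaction_fn(model)
  if (is.null(p0)) p0 <- (model$param_start + model$param_end) / 2
  if (is.null(v0)) v0 <- find_equilibrium(model) * 0.6 + 0.1
  x <- c(v0, p0)
  g <- function(x) {
    e <- max(abs(x[1L]), 1) * 1e-6
    c(f(x[1L], x[2L]),
      (f(x[1L] + e, x[2L]) - f(x[1L] - e, x[2L])) / (2 * e))
  }
  for (it in seq_len(200L)) {
    gv <- g(x)
    if (sqrt(sum(gv^2)) < tol) break
    J <- matrix(0, 2L, 2L)
    for (k in 1:2) {
      e <- max(abs(x[k]), 1) * 1e-6
      xp <- x; xp[k] <- xp[k] + e
      xm <- x; xm[k] <- xm[k] - e
      J[, k] <- (g(xp) - g(xm)) / (2 * e)
    }
    step <- tryCatch(solve(J, gv), error = function(e) NULL)
    if (is.null(step)) stop("fold search failed: singular Jacobian",
                            call. = FALSE)
    # damped update keeps the iteration on the branch for poor starts
    x <- x - if (sqrt(sum(step^2)) > 1) step / sqrt(sum(step^2)) else step
  }
  if (sqrt(sum(g(x)^2)) >= 1e-6)
    stop("fold search did not converge", call. = FALSE)
  list(param = x[2L], state = x[1L])
}

#' Derive per-realisation seeds from an ensemble seed
#'
#' Deterministic counter hash of `(base_seed, k)` (multiplicative mixing
#' modulo the Mersenne prime 2^31 - 1), so realisation `k` of an ensemble
#' can be regenerated without simulating the others.  The mapping is part
#' of the package's reproducibility contract and stable across versions.
#'
#' @param base_seed ensemble master seed (non-negative integer).
#' @param n number of realisations.
#' @return Numeric vector of `n` distinct seeds below 2^31.
#' @export
derive_seeds <- function(base_seed, n) {
  vapply(seq_len(n), function(k) {
    x <- (base_seed * 2654435761 + k * 40503) %% 2147483647
    x <- (x * 48271) %% 2147483647
    as.numeric(x)
  }, numeric(1))
}

#' Integrate a fast-slow stochastic lattice system
#'
#' Euler-Maruyama integration of
#' `X <- X + [f(X, p) + D Lap(X)] dt + sigma sqrt(dt) xi`, with iid standard
#' normal `xi` per site and `p <- p + epsilon dt`, from the homogeneous
#' equilibrium of the fast subsystem at `param_start` until the driver
#' reaches `param_end`.  Periodic boundaries.  Built-in reactions run in
#' compiled code with the package's own deterministic RNG; custom R-function
#' reactions run in a pure-R path using R's RNG (seeded from `config$seed`).
#' Either way, identical `(model, config)` give bit-identical output.
#'
#' @param model a `model_spec`.
#' @param config a `sim_config`.  `config$record_every` controls the raw
#'   recording stride (default 1 when at most ~4000 frames would be kept,
#'   otherwise about ten times `n_snapshots` frames).
#' @return A [lattice_series()] of the recorded raw trajectory (initial
#'   condition and final state always included), with the bifurcation
#'   parameter as driver and the time track attached as attribute `time`.
#' @seealso [downsample()], [simulate_tipping_data()], [make_ensemble()]
#' @export
simulate_fast_slow <- function(model, config) {
  stopifnot(inherits(model, "model_spec"), inherits(config, "sim_config"))
  co <- effective_coefs(model)
  if (config$dt > 1 / (4 * co$D) + 1e-12)
    stop("unstable configuration: dt = ", config$dt,
         " exceeds the diffusive stability bound h^2/(4D) = ",
         format(1 / (4 * co$D)), call. = FALSE)
  total_time <- (model$param_end - model$param_start) / model$epsilon
  n_steps <- ceiling(total_time / config$dt)
  record_every <- config$record_every
  if (is.null(record_every)) {
    record_every <- if (n_steps <= 4000L) 1L else
      max(1L, n_steps %/% (10L * config$n_snapshots))
  }
  v0 <- find_equilibrium(model)
  N <- model$lattice_n
  init <- matrix(v0, N, N)

  if (is.character(model$reaction)) {
    model_id <- match(model$reaction, c("harvest", "bistable"))
    pars <- if (model$reaction == "harvest") as.numeric(model$reaction_pars)
            else numeric(1)
    res <- .em_integrate_cpp(init, model_id, pars, co$D, co$sigma,
                             model$param_start, model$epsilon, config$dt,
                             as.integer(n_steps), as.integer(record_every),
                             config$seed, model$state_floor)
    k <- res$n_recorded
    data <- array(res$states[, seq_len(k)], dim = c(N, N, k))
    driver <- res$driver[seq_len(k)]
    times <- res$time[seq_len(k)]
  } else {
    f <- model$reaction
    rec_at <- unique(c(0L, seq.int(record_every, n_steps, by = record_every),
                       n_steps))
    k <- length(rec_at)
    data <- array(NA_real_, dim = c(N, N, k))
    driver <- times <- numeric(k)
    set.seed(config$seed)
    x <- init
    p <- model$param_start
    sig_dt <- co$sigma * sqrt(config$dt)
    data[, , 1L] <- x
    driver[1L] <- p
    slot <- 2L
    for (s in seq_len(n_steps)) {
      drift <- f(x, p) + co$D * discrete_laplacian(x)
      x <- x + drift * config$dt
      if (co$sigma > 0) x <- x + sig_dt * matrix(rnorm(N * N), N, N)
      if (is.finite(model$state_floor)) {
        low <- x < model$state_floor
        if (any(low)) x[low] <- 2 * model$state_floor - x[low]
      }
      p <- model$param_start + model$epsilon * (s * config$dt)
      if (s %% record_every == 0L || s == n_steps) {
        if (!all(is.finite(x)))
          stop("state became non-finite at step ", s,
               "; the integration is unstable -- reduce dt or the coupling",
               call. = FALSE)
        data[, , slot] <- x
        driver[slot] <- p
        times[slot] <- s * config$dt
        slot <- slot + 1L
      }
    }
  }
  out <- lattice_series(data, driver, driver_kind = "parameter",
                        model = if (is.character(model$reaction))
                          model$reaction else "custom")
  attr(out, "time") <- times
  out
}

#' Downsample a snapshot stack to realistic resolution
#'
#' Retains `n_snapshots` evenly spaced snapshots, always including the final
#' one; the driver (and time) tracks are subsampled identically.  Mirrors
#' the practice of thinning densely integrated trajectories to the sparse,
#' low-frequency sampling of real observations.
#'
#' @param raw a `lattice_series`.
#' @param n_snapshots number of snapshots to keep (`2 <= n <= T`).
#' @return A `lattice_series` of length `n_snapshots`.
#' @export
downsample <- function(raw, n_snapshots) {
  stopifnot(inherits(raw, "lattice_series"))
  T_len <- dim(raw$data)[3L]
  if (n_snapshots < 2) stop("`n_snapshots` must be >= 2", call. = FALSE)
  if (n_snapshots > T_len)
    stop("`n_snapshots` (", n_snapshots, ") exceeds series length (",
         T_len, ")", call. = FALSE)
  # round-half-up keeps indices strictly increasing whenever spacing >= 1
  idx <- floor(seq(1, T_len, length.out = n_snapshots) + 0.5)
  out <- lattice_series(raw$data[, , idx, drop = FALSE], raw$driver[idx],
                        driver_kind = raw$driver_kind, model = raw$model)
  if (!is.null(attr(raw, "time"))) attr(out, "time") <- attr(raw, "time")[idx]
  out
}

#' Simulate and downsample in one call
#'
#' Convenience wrapper: [simulate_fast_slow()] followed by [downsample()] to
#' `config$n_snapshots`.
#'
#' @inheritParams simulate_fast_slow
#' @return A `lattice_series` of length `config$n_snapshots`.
#' @export
simulate_tipping_data <- function(model, config) {
  downsample(simulate_fast_slow(model, config), config$n_snapshots)
}

#' Simulate an ensemble of independent realisations
#'
#' Realisation `k` uses a seed derived deterministically from
#' `(base_seed, k)` by a fixed counter hash, so the full ensemble is
#' reproducible from `base_seed` alone and single realisations can be
#' regenerated in isolation.
#'
#' @inheritParams simulate_fast_slow
#' @param n_realisations number of independent realisations.
#' @param base_seed ensemble master seed.
#' @return List of `n_realisations` downsampled [lattice_series()] objects;
#'   the derived seeds are attached as attribute `seeds`.
#' @export
make_ensemble <- function(model, config, n_realisations, base_seed) {
  if (n_realisations < 1) stop("`n_realisations` must be >= 1", call. = FALSE)
  seeds <- derive_seeds(base_seed, n_realisations)
  out <- vector("list", n_realisations)
  for (k in seq_len(n_realisations)) {
    cfg_k <- config
    cfg_k$seed <- seeds[k]
    out[[k]] <- tryCatch(simulate_tipping_data(model, cfg_k),
                         error = function(e)
                           stop("realisation ", k, ": ", conditionMessage(e),
                                call. = FALSE))
  }
  attr(out, "seeds") <- seeds
  out
}
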