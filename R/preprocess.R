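#' Spatial mean of each snapshot
#'
#' Reduces a snapshot stack to the univariate series of per-snapshot spatial
#' means, the standard scalar observable on which temporal indicators are
#' computed.  The driver track is carried through unchanged.
#'
#' @param series a [lattice_series()].
#' @return A [scalar_series()] of length `T`.
#' @export
spatial_mean_series <- function(series) {
  stopifnot(inherits(series, "lattice_series"))
  scalar_series(colMeans(series$data, dims = 2L), series$driver,
                driver_kind = series$driver_kind)
}

#' Linear detrending of a scalar series
#'
#' Removes the ordinary-least-squares line of the values on the driver.
#' Residuals sum to zero and are uncorrelated with the driver; the
#' operation is idempotent and unaffected by adding any line to the input.
#' Non-stationarity of the mean inflates window-based indicators, so series
#' are detrended before rolling statistics are computed.
#'
#' @param ts a [scalar_series()] of length at least 3.
#' @return A [scalar_series()] of residuals.
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "scalar_series"))
  if (length(ts$values) < 3L)
    stop("need at least 3 observations to detrend", call. = FALSE)
  res <- stats::residuals(stats::lm(ts$values ~ ts$driver))
  scalar_series(as.numeric(res), ts$driver, driver_kind = ts$driver_kind)
}

#' Uniform spatial-mean removal from each snapshot
#'
#' Subtracts each snapshot's own spatial mean from every one of its sites,
#' leaving within-snapshot deviations untouched.  This detrends the
#' spatio-temporal stack without introducing any window size or smoothing
#' bandwidth, which is why per-snapshot spatial indicators computed from the
#' residuals are invariant to window-size choices.
#'
#' @param series a [lattice_series()].
#' @return A [lattice_series()] of residual snapshots, each with spatial
#'   mean exactly zero.
#' @export
detrend_spatial_mean <- function(series) {
  stopifnot(inherits(series, "lattice_series"))
  m <- colMeans(series$data, dims = 2L)
  out <- series
  out$data <- sweep(series$data, 3L, m)
  out
}

#' Locate the tipping point from the largest sudden shift
#'
#' Finds the largest single-step change `|value[t+1] - value[t]|` of the
#' series.  If that jump exceeds `min_jump_fraction` of the series range the
#' driver value at the step's left endpoint is returned — the last driver
#' value before the collapse; otherwise `NA` (no tipping detected, a valid
#' outcome).  This formalises reading the transition off the spatial-mean
#' curve as the dominant discontinuity of the downsampled series.
#'
#' @param ts a [scalar_series()] of length at least 3.
#' @param min_jump_fraction jump threshold as a fraction of
#'   `max(values) - min(values)`, default 0.25.
#' @return Driver value at the tipping step, or `NA_real_`.
#' @export
estimate_tipping <- function(ts, min_jump_fraction = 0.25) {
  stopifnot(inherits(ts, "scalar_series"))
  v <- ts$values
  if (length(v) < 3L)
    stop("need at least 3 observations to locate a tipping point",
         call. = FALSE)
  jumps <- abs(diff(v))
  rng <- max(v) - min(v)
  i <- which.max(jumps)
  if (rng == 0 || jumps[i] <= min_jump_fraction * rng) return(NA_real_)
  ts$driver[i]
}

#' Restrict a series or trace to a driver interval
#'
#' Keeps exactly the entries whose driver value lies in
#' `[interval$lower, interval$upper]` (both ends inclusive).  For
#' window-dependent indicator traces the masked warm-up entries remain
#' masked; they are dropped later, at trend-analysis time.  Trend analysis
#' is always run on a subset that precedes the potential tipping locations.
#'
#' @param x a [scalar_series()] or [ews_trace()].
#' @param interval a [driver_interval()].
#' @return Object of the same class, restricted to the interval.
#' @export
select_subset <- function(x, interval) {
  stopifnot(inherits(interval, "driver_interval"))
  # inclusive bounds with a relative guard against floating-point driver
  # values sitting epsilon outside the interval
  tol <- 1e-9 * max(1, abs(interval$lower), abs(interval$upper))
  keep <- x$driver >= interval$lower - tol & x$driver <= interval$upper + tol
  if (!any(keep))
    stop("empty selection: driver range [",
         format(min(x$driver)), ", ", format(max(x$driver)),
         "] does not intersect [", interval$lower, ", ", interval$upper, "]",
         call. = FALSE)
  if (inherits(x, "scalar_series")) {
    scalar_series(x$values[keep], x$driver[keep], driver_kind = x$driver_kind)
  } else if (inherits(x, "ews_trace")) {
    ews_trace(x$values[keep], x$driver[keep], indicator = x$indicator,
              window_size = x$window_size, driver_kind = x$driver_kind)
  } else {
    stop("`x` must be a scalar_series or ews_trace", call. = FALSE)
  }
}
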