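# Temporal early warning indicators: statistics of a (detrended) scalar
# series over backwards rolling windows of W_s points.  The window at t
# covers indices t - W_s + 1 ... t (it includes the current point), under
# the assumption that the recent past approximates an ensemble at t.
# Entries with t < W_s are masked.

roll_apply <- function(ts, W_s, min_W, fn, indicator) {
  stopifnot(inherits(ts, "scalar_series"))
  T_len <- length(ts$values)
  W_s <- as.integer(W_s)
  if (W_s < min_W || W_s > T_len)
    stop("window length ", W_s, " outside the admissible range [", min_W,
         ", ", T_len, "]", call. = FALSE)
  vals <- rep(NA_real_, T_len)
  warned <- FALSE
  for (t in W_s:T_len) {
    w <- ts$values[(t - W_s + 1L):t]
    v <- fn(w)
    if (is.na(v) && !warned) {
      warning(indicator, ": undefined on a degenerate (constant) window; ",
              "masking", call. = FALSE)
      warned <- TRUE
    }
    vals[t] <- v
  }
  ews_trace(vals, ts$driver, indicator = indicator, window_size = W_s,
            driver_kind = ts$driver_kind)
}

#' Rolling variance
#'
#' Sample variance (denominator `W_s - 1`) over a backwards rolling window
#' ending at each point.  Rising variance is the classical signature of
#' critical slowing down: perturbations decay more slowly near the
#' bifurcation, so fluctuations accumulate.
#'
#' @param ts a detrended [scalar_series()].
#' @param W_s window length in points, `3 <= W_s <= T`.
#' @return An [ews_trace()] masked for `t < W_s`.
#' @export
rolling_variance <- function(ts, W_s) {
  roll_apply(ts, W_s, 3L, stats::var, "variance")
}

#' Rolling skewness
#'
#' Central-moment skewness `m3 / m2^(3/2)` (population denominators `W_s`)
#' over a backwards rolling window.  Asymmetric fluctuation towards the
#' alternative state can skew the distribution before a transition.
#' Constant windows have undefined skewness and are masked with a warning.
#'
#' @inheritParams rolling_variance
#' @return An [ews_trace()].
#' @export
rolling_skewness <- function(ts, W_s) {
  roll_apply(ts, W_s, 3L, function(w) {
    d <- w - mean(w)
    m2 <- mean(d^2)
    if (m2 == 0) return(NA_real_)
    mean(d^3) / m2^1.5
  }, "skewness")
}

#' Rolling lag-1 autoregression coefficient
#'
#' Least-squares slope (with intercept) of `X_t` on `X_{t-1}` over the pairs
#' inside each backwards window: the AR(1) coefficient, which approaches 1
#' as recovery from perturbations slows near a transition.
#'
#' @inheritParams rolling_variance
#' @param W_s window length in points, `4 <= W_s <= T`.
#' @return An [ews_trace()].
#' @export
rolling_ar1 <- function(ts, W_s) {
  roll_apply(ts, W_s, 4L, function(w) {
    x <- w[-length(w)]
    y <- w[-1L]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) return(NA_real_)
    sum((x - mean(x)) * (y - mean(y))) / sxx
  }, "ar1")
}

#' Rolling lag-1 autocorrelation
#'
#' Plug-in lag-1 autocorrelation over each backwards window:
#' `sum((x_s - m)(x_{s+1} - m)) / sum((x_s - m)^2)` with the window mean
#' `m`.  Like the AR(1) coefficient it rises towards 1 under critical
#' slowing down; the biased (plug-in) normalisation is used.
#'
#' @inheritParams rolling_ar1
#' @return An [ews_trace()].
#' @export
rolling_acf1 <- function(ts, W_s) {
  roll_apply(ts, W_s, 4L, function(w) {
    d <- w - mean(w)
    s2 <- sum(d^2)
    if (s2 == 0) return(NA_real_)
    sum(d[-length(d)] * d[-1L]) / s2
  }, "acf1")
}

#' Convert a window percentage to a window length
#'
#' `W_s = round(p/100 * T)`, floored at `min_W` (3 by default), so window
#' sizes can be stated as percentages of the series length.
#'
#' @param pct window size as a percentage of the series length.
#' @param T_len series length.
#' @param min_W smallest admissible window.
#' @return Integer window length.
#' @export
window_from_pct <- function(pct, T_len, min_W = 3L) {
  max(as.integer(min_W), as.integer(round(pct / 100 * T_len)))
}
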