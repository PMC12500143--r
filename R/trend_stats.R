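# Trend quantification and significance.  An indicator's trend against the
# driver is measured with Kendall's tau; its significance with the
# Hamed-Rao modified Mann-Kendall test, whose score variance is inflated by
# the rank autocorrelations of the detrended series to account for the
# serial dependence that overlapping rolling windows induce.

#' Kendall's tau between driver and indicator
#'
#' Tie-corrected (tau-b) rank correlation.  Being a rank statistic it is
#' invariant under strictly increasing transformations of `x`, so the trend
#' against the bifurcation parameter equals the trend against time whenever
#' the parameter drifts monotonically.  Pairs with a missing value in
#' either argument (e.g. the masked warm-up of a windowed indicator) are
#' dropped.
#'
#' @param x driver values.
#' @param y indicator values.
#' @return Kendall's tau in `[-1, 1]`; `NA` with a warning when fewer than
#'   3 complete pairs remain or `y` is completely tied.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    warning("fewer than 3 complete pairs; Kendall's tau undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (length(unique(y)) == 1L) {
    warning("`y` is constant; Kendall's tau undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "kendall")
}

#' Sen's slope
#'
#' Median of all pairwise slopes `(y_j - y_i) / (j - i)`, `i < j`: the
#' robust trend estimate used to detrend a series before its rank
#' autocorrelations are estimated in the modified Mann-Kendall test.
#'
#' @param y numeric vector, length at least 2 (missing values dropped).
#' @return Scalar slope per unit index.
#' @export
sen_slope <- function(y) {
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  i <- seq_len(n)
  dy <- outer(y, y, "-")
  di <- outer(i, i, "-")
  stats::median(dy[di > 0] / di[di > 0])
}

# Mann-Kendall score and its tie-corrected null variance
mk_score <- function(y) {
  n <- length(y)
  s <- sum(sign(outer(y, y, "-"))[lower.tri(matrix(0, n, n))])
  ties <- table(y)
  ties <- ties[ties > 1L]
  var0 <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  list(s = s, var0 = var0)
}

# tau-b from the score, with tie corrections (x = 1..n has no ties)
mk_tau <- function(y, s) {
  n <- length(y)
  n0 <- n * (n - 1) / 2
  ties <- table(y)
  ties <- ties[ties > 1L]
  n1 <- sum(ties * (ties - 1) / 2)
  denom <- sqrt((n0 - n1) * n0)
  if (denom == 0) return(0)
  s / denom
}

#' Modified Mann-Kendall trend test (Hamed-Rao)
#'
#' Tests for a monotone trend in `y` (in its given order, i.e. against
#' time/driver rank).  The classical Mann-Kendall score
#' `S = sum_{i<j} sign(y_j - y_i)` has tie-corrected null variance
#' `Var0(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18`.  Serial dependence
#' inflates the true variance, so `Var0` is multiplied by the Hamed-Rao
#' correction factor
#' `n/n_s* = 1 + 2/(n(n-1)(n-2)) * sum_k (n-k)(n-k-1)(n-k-2) rho_s(k)`,
#' where `rho_s(k)` are the lag-`k` autocorrelations of the *ranks* of the
#' Sen-slope-detrended series, summed over the lags (capped at `n/4`) whose
#' autocorrelation exceeds the two-sided 5% white-noise bound
#' `1.96/sqrt(n)`.  A computed factor below 1 is floored at 1 (safeguard
#' against variance deflation).  The standardised score uses the continuity
#' correction `Z = (S - sign(S)) / sqrt(Var(S))` and a two-sided normal
#' p-value.
#'
#' @param y indicator values in series order (missing values dropped).
#' @param alpha significance level, default 0.05 (two-sided).
#' @param correction `"hamed-rao"` (default) or `"none"` for the classical
#'   test (equivalently: all rank autocorrelations forced to zero).
#' @return An object of class `trend_result`: a list with `tau`,
#'   `s_statistic`, `var_s`, `z`, `p_value`, `significant`, `n_used` and
#'   `correction_factor`.
#' @export
modified_mann_kendall <- function(y, alpha = 0.05,
                                  correction = c("hamed-rao", "none")) {
  correction <- match.arg(correction)
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 10L)
    stop("the asymptotic Mann-Kendall test needs n >= 10 (got n = ", n,
         ")", call. = FALSE)
  if (length(unique(y)) == 1L) {
    warning("constant series: no trend, reported non-significant",
            call. = FALSE)
    return(structure(list(tau = 0, s_statistic = 0, var_s = NA_real_,
                          z = 0, p_value = 1, significant = FALSE,
                          n_used = n, correction_factor = 1,
                          alpha = alpha),
                     class = "trend_result"))
  }
  mk <- mk_score(y)
  cf <- 1
  if (correction == "hamed-rao") {
    detr <- y - sen_slope(y) * seq_len(n)
    r <- rank(detr)
    max_lag <- max(1L, n %/% 4L)
    rho <- as.numeric(stats::acf(r, lag.max = max_lag, plot = FALSE,
                                 demean = TRUE)$acf)[-1L]
    rho[!is.finite(rho)] <- 0   # constant detrended series has no ACF
    keep <- abs(rho) > 1.96 / sqrt(n)
    k <- which(keep)
    if (length(k)) {
      cf <- 1 + 2 / (n * (n - 1) * (n - 2)) *
        sum((n - k) * (n - k - 1) * (n - k - 2) * rho[k])
      if (cf < 1) cf <- 1
    }
  }
  var_s <- mk$var0 * cf
  z <- if (mk$s == 0) 0 else (mk$s - sign(mk$s)) / sqrt(var_s)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(tau = mk_tau(y, mk$s), s_statistic = mk$s, var_s = var_s,
                 z = z, p_value = p, significant = p < alpha, n_used = n,
                 correction_factor = cf, alpha = alpha),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("<trend_result> tau = ", format(x$tau, digits = 3),
      ", S = ", x$s_statistic,
      ", Z = ", format(x$z, digits = 3),
      ", p = ", format(x$p_value, digits = 3),
      if (x$significant) " *" else "",
      " (n = ", x$n_used, ", correction ",
      format(x$correction_factor, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Trend of an indicator trace against its driver
#'
#' Convenience wrapper: drops masked entries, computes Kendall's tau of the
#' indicator against the driver and the modified Mann-Kendall significance
#' of the trend, returning both in one `trend_result`.
#'
#' @param trace an [ews_trace()] (ideally already restricted to the
#'   pre-tipping driver subset with [select_subset()]).
#' @inheritParams modified_mann_kendall
#' @return A `trend_result` whose `tau` is Kendall's tau of the trace
#'   values against the driver.
#' @export
trend_test <- function(trace, alpha = 0.05,
                       correction = c("hamed-rao", "none")) {
  stopifnot(inherits(trace, "ews_trace"))
  ok <- !is.na(trace$values)
  res <- modified_mann_kendall(trace$values[ok], alpha = alpha,
                               correction = correction)
  # tau against the (possibly tied) driver rather than pure series order
  kt <- suppressWarnings(kendall_tau(trace$driver[ok], trace$values[ok]))
  if (!is.na(kt)) res$tau <- kt
  res
}
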