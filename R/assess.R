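# Performance assessment: window-size sensitivity sweeps over one
# realisation, and ensemble summaries (mean/std of Kendall's tau, percent
# of significant trends) over repeated realisations.

#' Indicator routing table
#'
#' One row per supported indicator, declaring its class (`temporal`,
#' `spatial`, `eigen`), whether it is window-based, and the detrending
#' route its input takes: temporal indicators consume the *linearly
#' detrended spatial-mean* series; per-snapshot spatial indicators and the
#' eigenvalue indicators consume the *spatial-mean-removed* snapshot stack.
#' [window_sensitivity()] consults this table, so the routing is
#' configuration, not control flow.
#'
#' @return A data.frame with columns `indicator`, `class`, `windowed`,
#'   `detrend` and `expected_direction` (the direction critical slowing
#'   down is expected to push the indicator; reported alongside the trend,
#'   never folded into the p-value).
#' @export
indicator_table <- function() {
  data.frame(
    indicator = c("variance", "skewness", "ar1", "acf1",
                  "spatial_variance", "spatial_skewness",
                  "spatial_correlation", "eigen_max", "eigen_fraction"),
    class = c(rep("temporal", 4L), rep("spatial", 3L), rep("eigen", 2L)),
    windowed = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    detrend = c(rep("linear_mean", 4L), rep("spatial_mean", 5L)),
    expected_direction = c("increase", "either", "increase", "increase",
                           "increase", "either", "increase", "increase",
                           "increase"),
    stringsAsFactors = FALSE
  )
}

#' Compute one named indicator on a snapshot stack
#'
#' Applies the detrending route declared in [indicator_table()] and
#' evaluates the indicator, returning a driver-aligned trace.  Temporal
#' indicators are computed on the linearly detrended spatial-mean series;
#' spatial and eigenvalue indicators on the spatial-mean-removed stack.
#'
#' @param series a [lattice_series()] (raw; detrending is applied here).
#' @param indicator one of the names in [indicator_table()].
#' @param W_s window length in snapshots (ignored for window-free
#'   indicators).
#' @param boundary boundary rule for Moran's I.
#' @return An [ews_trace()].
#' @export
ews_indicator <- function(series, indicator, W_s = 0L,
                          boundary = c("periodic", "truncate")) {
  stopifnot(inherits(series, "lattice_series"))
  boundary <- match.arg(boundary)
  tab <- indicator_table()
  if (!indicator %in% tab$indicator)
    stop("unknown indicator \"", indicator, "\"; see indicator_table()",
         call. = FALSE)
  row <- tab[tab$indicator == indicator, ]
  if (row$windowed && W_s < 2L)
    stop("indicator \"", indicator, "\" needs a window length W_s",
         call. = FALSE)
  if (row$class == "temporal") {
    ts <- detrend_linear(spatial_mean_series(series))
    return(switch(indicator,
                  variance = rolling_variance(ts, W_s),
                  skewness = rolling_skewness(ts, W_s),
                  ar1 = rolling_ar1(ts, W_s),
                  acf1 = rolling_acf1(ts, W_s)))
  }
  resid <- detrend_spatial_mean(series)
  if (row$class == "eigen") {
    pair <- eigen_ews(resid, W_s)
    return(if (indicator == "eigen_max") pair$lambda_max else
             pair$lambda_frac)
  }
  T_len <- dim(resid$data)[3L]
  fn <- switch(indicator,
               spatial_variance = spatial_variance,
               spatial_skewness = function(s)
                 suppressWarnings(spatial_skewness(s)),
               spatial_correlation = function(s)
                 suppressWarnings(morans_i(s, boundary)))
  vals <- vapply(seq_len(T_len), function(t) fn(resid$data[, , t]),
                 numeric(1))
  ews_trace(vals, resid$driver, indicator = indicator, window_size = 0L,
            driver_kind = resid$driver_kind)
}

#' Window-size sensitivity sweep for one realisation
#'
#' For every (indicator, window percentage) pair: compute the indicator on
#' the appropriately detrended data, restrict it to the pre-tipping driver
#' subset, and quantify its trend (Kendall's tau against the driver, with
#' modified Mann-Kendall significance).  Window-free indicators are
#' computed once and replicated across the grid — their trend is invariant
#' to the window choice by construction.  Cells whose window leaves too few
#' points for the asymptotic test are marked invalid with a reason; the
#' sweep continues.
#'
#' @param series a [lattice_series()] (one realisation, raw).
#' @param indicators character vector of indicator names
#'   ([indicator_table()]); defaults to all nine.
#' @param window_pcts window sizes as percentages of the series length,
#'   e.g. `seq(25, 50, length.out = 9)`.
#' @param subset a [driver_interval()] preceding the tipping point.
#' @param alpha significance level.
#' @param boundary boundary rule for Moran's I.
#' @return A data.frame of class `sensitivity_grid` with one row per cell:
#'   `indicator`, `window_pct`, `W_s`, `tau`, `z`, `p_value`,
#'   `significant`, `n_used`, `valid`, `reason`.
#' @export
window_sensitivity <- function(series, indicators = indicator_table()$indicator,
                               window_pcts = seq(25, 50, length.out = 9),
                               subset, alpha = 0.05,
                               boundary = "periodic") {
  stopifnot(inherits(series, "lattice_series"),
            inherits(subset, "driver_interval"))
  if (length(indicators) == 0L)
    stop("`indicators` must name at least one indicator", call. = FALSE)
  tab <- indicator_table()
  unknown <- setdiff(indicators, tab$indicator)
  if (length(unknown))
    stop("unknown indicator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  T_len <- dim(series$data)[3L]

  cell <- function(indicator, pct, trace) {
    out <- data.frame(indicator = indicator, window_pct = pct,
                      W_s = trace$window_size, tau = NA_real_, z = NA_real_,
                      p_value = NA_real_, significant = NA, n_used = 0L,
                      valid = FALSE, reason = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      sub <- select_subset(trace, subset)
      tr <- suppressWarnings(trend_test(sub, alpha = alpha))
      out$tau <- tr$tau; out$z <- tr$z; out$p_value <- tr$p_value
      out$significant <- tr$significant; out$n_used <- tr$n_used
      out$valid <- TRUE
      out
    }, error = function(e) {
      out$reason <- conditionMessage(e)
      out
    })
    res
  }

  rows <- list()
  for (ind in indicators) {
    windowed <- tab$windowed[tab$indicator == ind]
    if (!windowed) {
      trace <- ews_indicator(series, ind, boundary = boundary)
      for (pct in window_pcts) rows[[length(rows) + 1L]] <-
          cell(ind, pct, trace)
    } else {
      for (pct in window_pcts) {
        W_s <- window_from_pct(pct, T_len)
        trace <- tryCatch(ews_indicator(series, ind, W_s = W_s,
                                        boundary = boundary),
                          error = function(e) e)
        rows[[length(rows) + 1L]] <-
          if (inherits(trace, "error")) {
            data.frame(indicator = ind, window_pct = pct, W_s = W_s,
                       tau = NA_real_, z = NA_real_, p_value = NA_real_,
                       significant = NA, n_used = 0L, valid = FALSE,
                       reason = conditionMessage(trace),
                       stringsAsFactors = FALSE)
          } else cell(ind, pct, trace)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "T_len") <- T_len
  class(out) <- c("sensitivity_grid", "data.frame")
  out
}

#' Ensemble summary of trend results
#'
#' Combines the sensitivity grids of repeated realisations into the
#' per-indicator summary used to compare indicators: mean and standard
#' deviation of Kendall's tau, and the percentage of realisations whose
#' trend is significant, per (indicator, window percentage) cell.  Relying
#' on the percent-significant across realisations is more informative than
#' the p-value of any single realisation.  With a single realisation the
#' standard deviation is 0 and the realisation's p-value is carried
#' through (the empirical-data mode).
#'
#' @param grids list of `sensitivity_grid` objects with identical
#'   (indicator, window_pct) layout.
#' @return A data.frame of class `assessment_table` with columns
#'   `indicator`, `window_pct`, `mean_tau`, `sd_tau`, `pct_significant`,
#'   `n_realisations` (and `p_value` when `n_realisations == 1`).
#' @export
ensemble_summary <- function(grids) {
  if (inherits(grids, "sensitivity_grid")) grids <- list(grids)
  if (length(grids) < 1L) stop("need at least one realisation", call. = FALSE)
  key0 <- paste(grids[[1L]]$indicator, grids[[1L]]$window_pct)
  for (g in grids)
    if (!identical(paste(g$indicator, g$window_pct), key0))
      stop("sensitivity grids have mismatching shapes", call. = FALSE)
  all <- do.call(rbind, lapply(seq_along(grids), function(k) {
    g <- as.data.frame(grids[[k]])
    g$realisation <- k
    g
  }))
  sp <- split(all, list(all$indicator, all$window_pct), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    ok <- d$valid & !is.na(d$tau)
    data.frame(indicator = d$indicator[1L], window_pct = d$window_pct[1L],
               mean_tau = if (any(ok)) mean(d$tau[ok]) else NA_real_,
               sd_tau = if (sum(ok) > 1L) stats::sd(d$tau[ok]) else 0,
               pct_significant = if (any(ok))
                 100 * mean(d$significant[ok]) else NA_real_,
               n_realisations = length(grids),
               p_value = if (length(grids) == 1L) d$p_value[1L] else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$indicator, out$window_pct), ]
  rownames(out) <- NULL
  class(out) <- c("assessment_table", "data.frame")
  out
}

#' Window-free indicator summary
#'
#' Collapses an [ensemble_summary()] to one row per window-free indicator
#' (their cells are identical across the window grid), giving the compact
#' mean-tau / std / percent-significant comparison table for spatial
#' variance, spatial skewness and spatial correlation.
#'
#' @param summary an `assessment_table`.
#' @return A data.frame with one row per window-free indicator.
#' @export
window_free_table <- function(summary) {
  stopifnot(inherits(summary, "assessment_table"))
  tab <- indicator_table()
  free <- tab$indicator[!tab$windowed]
  out <- summary[summary$indicator %in% free, ]
  out <- out[!duplicated(out$indicator), ]
  out$window_pct <- NULL
  rownames(out) <- NULL
  out
}

#' Plot a window-sensitivity summary
#'
#' Two-panel view of an ensemble summary: mean Kendall's tau (with a
#' +/- 1 sd ribbon) against window percentage, and the percentage of
#' significant trends against window percentage.  Requires ggplot2.
#'
#' @param summary an `assessment_table`.
#' @return A ggplot object (patchwork-free: the two panels are facets).
#' @export
plot_sensitivity <- function(summary) {
  stopifnot(inherits(summary, "assessment_table"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- as.data.frame(summary)
  long <- rbind(
    data.frame(indicator = d$indicator, window_pct = d$window_pct,
               panel = "mean Kendall's tau", y = d$mean_tau,
               ymin = d$mean_tau - d$sd_tau, ymax = d$mean_tau + d$sd_tau),
    data.frame(indicator = d$indicator, window_pct = d$window_pct,
               panel = "% significant", y = d$pct_significant,
               ymin = NA_real_, ymax = NA_real_))
  ggplot2::ggplot(long, ggplot2::aes(x = window_pct, y = y,
                                     colour = indicator)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ymin, ymax = ymax,
                                      fill = indicator),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "window size (% of series length)", y = NULL)
}
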