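#' Spatio-temporal snapshot stack
#'
#' A `lattice_series` holds `T` snapshots of an `N x N` lattice of state
#' values together with an aligned *driver* track: the value, per snapshot,
#' of the quantity the indicators are ultimately correlated against.  For
#' synthetic data the driver is the bifurcation parameter (which drifts
#' linearly with time); for empirical data it may be plain time or a spatial
#' index along a gradient.
#'
#' @param data numeric array of dimension `c(N, N, T)`; `data[, , t]` is the
#'   snapshot at position `t` along the series.
#' @param driver numeric vector of length `T`, non-decreasing.
#' @param driver_kind one of `"parameter"`, `"time"`, `"spatial_index"`.
#' @param model optional character label of the generating model.
#'
#' @return An object of class `lattice_series` with elements `data`,
#'   `driver`, `driver_kind` and `model`.
#' @seealso [scalar_series()], [simulate_fast_slow()], [spatial_mean_series()]
#' @export
lattice_series <- function(data, driver, driver_kind = c("parameter", "time",
                                                         "spatial_index"),
                           model = NULL) {
  driver_kind <- match.arg(driver_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (N x N x T)", call. = FALSE)
  d <- dim(data)
  if (d[1L] != d[2L])
    stop("lattice snapshots must be square; got ", d[1L], " x ", d[2L],
         call. = FALSE)
  if (d[1L] < 2L)
    stop("lattice side must be at least 2", call. = FALSE)
  if (length(driver) != d[3L])
    stop("`driver` length (", length(driver), ") does not match the number ",
         "of snapshots (", d[3L], ")", call. = FALSE)
  if (anyNA(data) || !all(is.finite(data)))
    stop("`data` contains missing or non-finite values", call. = FALSE)
  if (anyNA(driver) || is.unsorted(driver))
    stop("`driver` must be non-decreasing with no missing values",
         call. = FALSE)
  structure(list(data = data, driver = as.numeric(driver),
                 driver_kind = driver_kind, model = model),
            class = "lattice_series")
}

#' @export
print.lattice_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<lattice_series> ", d[3L], " snapshots of a ", d[1L], "x", d[2L],
      " lattice\n", sep = "")
  cat("  driver (", x$driver_kind, "): ",
      format(x$driver[1L], digits = 4), " ... ",
      format(x$driver[d[3L]], digits = 4), "\n", sep = "")
  if (!is.null(x$model)) cat("  model: ", x$model, "\n", sep = "")
  invisible(x)
}

#' @export
dim.lattice_series <- function(x) dim(x$data)

#' Univariate series with an aligned driver track
#'
#' The scalar analogue of [lattice_series()]: typically the spatial mean of a
#' snapshot stack, on which the temporal indicators are computed.
#'
#' @param values numeric vector of observations.
#' @param driver numeric vector of the same length, non-decreasing.
#' @inheritParams lattice_series
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(values, driver,
                          driver_kind = c("parameter", "time",
                                          "spatial_index")) {
  driver_kind <- match.arg(driver_kind)
  if (length(values) != length(driver))
    stop("`values` and `driver` must have equal length", call. = FALSE)
  if (anyNA(driver) || is.unsorted(driver))
    stop("`driver` must be non-decreasing with no missing values",
         call. = FALSE)
  structure(list(values = as.numeric(values), driver = as.numeric(driver),
                 driver_kind = driver_kind),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat("<scalar_series> length ", length(x$values), ", driver (",
      x$driver_kind, ") ", format(x$driver[1L], digits = 4), " ... ",
      format(x$driver[length(x$driver)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
length.scalar_series <- function(x) length(x$values)

#' @export
as.data.frame.scalar_series <- function(x, ...) {
  data.frame(driver = x$driver, value = x$values)
}

#' One indicator evaluated along a series
#'
#' An `ews_trace` stores the value of one early warning indicator at every
#' position of the series it was computed from.  Window-dependent indicators
#' are undefined until a full backwards window is available, so entries with
#' `t < window_size` are masked (`NA`) and flagged invalid.
#'
#' @param values numeric vector; `NA` where the indicator is undefined.
#' @param driver aligned driver track (same length).
#' @param indicator character name of the indicator.
#' @param window_size window length in snapshots; `0` for window-free
#'   indicators.
#' @param driver_kind driver interpretation, as in [lattice_series()].
#' @return An object of class `ews_trace` with a logical `valid` element.
#' @export
ews_trace <- function(values, driver, indicator, window_size = 0L,
                      driver_kind = "parameter") {
  if (length(values) != length(driver))
    stop("`values` and `driver` must have equal length", call. = FALSE)
  structure(list(values = as.numeric(values), driver = as.numeric(driver),
                 indicator = indicator, window_size = as.integer(window_size),
                 valid = !is.na(values), driver_kind = driver_kind),
            class = "ews_trace")
}

#' @export
print.ews_trace <- function(x, ...) {
  cat("<ews_trace> ", x$indicator,
      if (x$window_size > 0L) paste0(" (window ", x$window_size, ")"),
      ": ", sum(x$valid), "/", length(x$values), " valid entries\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ews_trace <- function(x, ...) {
  data.frame(driver = x$driver, value = x$values, valid = x$valid,
             indicator = x$indicator, window_size = x$window_size)
}

#' Inclusive driver interval
#'
#' Closed interval of driver values used to restrict an indicator trace to
#' the stretch preceding the tipping point before trend analysis.
#'
#' @param lower,upper interval bounds, `lower < upper`; both inclusive.
#' @return An object of class `driver_interval`.
#' @export
driver_interval <- function(lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("need finite `lower` < `upper`", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "driver_interval")
}

#' @export
print.driver_interval <- function(x, ...) {
  cat("<driver_interval> [", x$lower, ", ", x$upper, "]\n", sep = "")
  invisible(x)
}
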