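# Plain-text on-disk format for snapshot stacks, configuration handling,
# and the end-to-end pipeline.
#
# A lattice series is stored as a directory containing
#   snapshot_0001.csv ... snapshot_TTTT.csv   (N x N values, no header,
#                                              row i / column j, comma-sep)
#   manifest.csv                              (columns: file, driver)
#   series.yaml                               (driver_kind, n_side,
#                                              n_snapshots, model)
# Snapshots are time-ordered through the manifest, not the file names.

#' Write a lattice series to a directory
#'
#' @param series a [lattice_series()].
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @seealso [read_lattice_series()]
#' @export
write_lattice_series <- function(series, path) {
  stopifnot(inherits(series, "lattice_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$data)
  files <- sprintf("snapshot_%04d.csv", seq_len(d[3L]))
  for (t in seq_len(d[3L]))
    utils::write.table(series$data[, , t], file.path(path, files[t]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(file = files, driver = series$driver),
                   file.path(path, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(list(driver_kind = series$driver_kind,
                        n_side = d[1L], n_snapshots = d[3L],
                        model = series$model),
                   file.path(path, "series.yaml"))
  invisible(path)
}

#' Read a lattice series from a directory
#'
#' Reads the dialect written by [write_lattice_series()].  A directory
#' holding only snapshot CSVs (no manifest, no metadata) is accepted with a
#' warning: snapshots are ordered by file name and the driver defaults to
#' the time index `0 ... T-1`.
#'
#' @param path directory containing the series.
#' @return A validated [lattice_series()].
#' @export
read_lattice_series <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  man_path <- file.path(path, "manifest.csv")
  meta_path <- file.path(path, "series.yaml")
  if (file.exists(man_path)) {
    man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
    if (!all(c("file", "driver") %in% names(man)))
      stop(man_path, ": manifest must have columns `file` and `driver`",
           call. = FALSE)
    missing <- man$file[!file.exists(file.path(path, man$file))]
    if (length(missing))
      stop(path, ": manifest lists ", nrow(man), " snapshots but ",
           length(missing), " file(s) are missing: ",
           paste(utils::head(missing, 3L), collapse = ", "),
           if (length(missing) > 3L) ", ...", call. = FALSE)
    files <- man$file
    driver <- man$driver
  } else {
    files <- sort(list.files(path, pattern = "^snapshot_.*\\.csv$"))
    if (!length(files))
      stop(path, ": no manifest.csv and no snapshot_*.csv files",
           call. = FALSE)
    driver <- seq_along(files) - 1
    warning(path, ": no manifest; using file order and a 0-based time ",
            "index as driver", call. = FALSE)
  }
  snaps <- lapply(file.path(path, files), function(f) {
    m <- as.matrix(utils::read.table(f, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    m
  })
  dims <- vapply(snaps, dim, integer(2))
  if (any(dims != dims[, 1L]))
    stop(path, ": snapshot dimensions are inconsistent (",
         files[which(colSums(dims != dims[, 1L]) > 0)[1L]], ")",
         call. = FALSE)
  if (is.unsorted(driver))
    stop(path, ": manifest driver values are not non-decreasing",
         call. = FALSE)
  kind <- "time"
  model <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$driver_kind)) kind <- meta$driver_kind
    if (!is.null(meta$n_snapshots) && meta$n_snapshots != length(files))
      stop(meta_path, ": metadata records ", meta$n_snapshots,
           " snapshots but ", length(files), " are present", call. = FALSE)
    model <- meta$model
  } else if (file.exists(man_path)) {
    warning(path, ": no series.yaml; assuming driver_kind = \"time\"",
            call. = FALSE)
  }
  data <- array(unlist(snaps), dim = c(dims[1L, 1L], dims[2L, 1L],
                                       length(snaps)))
  lattice_series(data, driver, driver_kind = kind, model = model)
}

#' Assemble a full run configuration
#'
#' Collects everything a reproducible assessment run needs: the model, the
#' integration settings, the analysis subset, the window grid, the
#' indicator list, the significance level and the ensemble seeds.  A
#' configuration round-trips losslessly through YAML, and every pipeline
#' run writes its resolved copy next to its outputs.
#'
#' @param model `"harvest"`, `"bistable"`, or a [model_spec()].
#' @param model_args named list of overrides passed to [harvest_model()] /
#'   [bistable_model()] when `model` is a name.
#' @param dt,n_snapshots integration settings (see [sim_config()]).
#' @param subset_lower,subset_upper analysis interval of the driver
#'   (defaults: the model-specific pre-tipping intervals).
#' @param window_pcts window-size grid in percent.
#' @param indicators indicator names, see [indicator_table()].
#' @param alpha significance level.
#' @param n_realisations ensemble size.
#' @param base_seed ensemble master seed.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(model = "harvest", model_args = list(), dt = 0.01,
                       n_snapshots = 40L, subset_lower = NULL,
                       subset_upper = NULL,
                       window_pcts = seq(25, 50, length.out = 9),
                       indicators = indicator_table()$indicator,
                       alpha = 0.05, n_realisations = 1L, base_seed = 1L) {
  if (is.character(model)) {
    builder <- switch(model, harvest = harvest_model,
                      bistable = bistable_model,
                      stop("unknown model \"", model, "\"", call. = FALSE))
    spec <- do.call(builder, model_args)
  } else {
    stopifnot(inherits(model, "model_spec"))
    spec <- model
    model <- if (is.character(spec$reaction)) spec$reaction else "custom"
  }
  if (length(indicators) == 0L)
    stop("`indicators` must name at least one indicator", call. = FALSE)
  unknown <- setdiff(indicators, indicator_table()$indicator)
  if (length(unknown))
    stop("unknown indicator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(subset_lower))
    subset_lower <- switch(model, harvest = 1, spec$param_start)
  if (is.null(subset_upper))
    subset_upper <- switch(model, harvest = 2.55,
                           spec$param_start +
                             0.85 * (spec$param_end - spec$param_start))
  structure(list(model = model, model_spec = spec, model_args = model_args,
                 dt = dt, n_snapshots = as.integer(n_snapshots),
                 subset_lower = subset_lower, subset_upper = subset_upper,
                 window_pcts = window_pcts, indicators = indicators,
                 alpha = alpha, n_realisations = as.integer(n_realisations),
                 base_seed = base_seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] arguments
#'   (unstated values take the documented defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "model_spec")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop(path, ": unknown configuration field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, raw)
}

resolved_config_list <- function(config) {
  spec <- config$model_spec
  list(model = config$model,
       model_args = config$model_args,
       model_resolved = list(
         coupling = spec$coupling, noise_sigma = spec$noise_sigma,
         param_name = spec$param_name, param_start = spec$param_start,
         param_end = spec$param_end, epsilon = spec$epsilon,
         lattice_n = spec$lattice_n, scaling = spec$scaling, h = spec$h),
       dt = config$dt, n_snapshots = config$n_snapshots,
       subset_lower = config$subset_lower,
       subset_upper = config$subset_upper,
       window_pcts = as.numeric(config$window_pcts),
       indicators = config$indicators, alpha = config$alpha,
       n_realisations = config$n_realisations,
       base_seed = config$base_seed)
}

#' Run the full assessment pipeline
#'
#' Simulates an ensemble, estimates the tipping location of each
#' realisation from its spatial-mean series, runs the window-sensitivity
#' sweep on each realisation over the configured pre-tipping subset, and
#' summarises the ensemble.  When `out_dir` is given, writes
#' `trend_results.csv` (every cell of every realisation),
#' `assessment_table.csv`, `tipping.csv` and `resolved_config.yaml`;
#' identical configurations and seeds reproduce the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return A list with elements `summary` (the `assessment_table`),
#'   `grids` (per-realisation `sensitivity_grid`s), `tipping` (estimated
#'   tipping driver value per realisation) and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  cfg <- sim_config(dt = config$dt, seed = config$base_seed,
                    n_snapshots = config$n_snapshots)
  say("simulating ", config$n_realisations, " realisation(s) of the ",
      config$model, " model ...")
  ens <- make_ensemble(config$model_spec, cfg, config$n_realisations,
                       config$base_seed)
  subset <- driver_interval(config$subset_lower, config$subset_upper)
  tipping <- numeric(config$n_realisations)
  grids <- vector("list", config$n_realisations)
  for (k in seq_along(ens)) {
    tipping[k] <- estimate_tipping(spatial_mean_series(ens[[k]]))
    grids[[k]] <- tryCatch(
      window_sensitivity(ens[[k]], indicators = config$indicators,
                         window_pcts = config$window_pcts, subset = subset,
                         alpha = config$alpha),
      error = function(e) stop("assessment stage, realisation ", k, ": ",
                               conditionMessage(e), call. = FALSE))
    say("  realisation ", k, ": tipping at ",
        config$model_spec$param_name, " = ", format(tipping[k], digits = 4))
  }
  summary <- ensemble_summary(grids)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    all_rows <- do.call(rbind, lapply(seq_along(grids), function(k) {
      g <- as.data.frame(grids[[k]]); g$realisation <- k; g
    }))
    utils::write.csv(all_rows, file.path(out_dir, "trend_results.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(summary),
                     file.path(out_dir, "assessment_table.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(realisation = seq_along(tipping),
                                tipping_driver = tipping),
                     file.path(out_dir, "tipping.csv"), row.names = FALSE)
    yaml::write_yaml(resolved_config_list(config),
                     file.path(out_dir, "resolved_config.yaml"))
  }
  list(summary = summary, grids = grids, tipping = tipping, config = config)
}
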