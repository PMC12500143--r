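test_that("indicator dispatch routes detrending correctly", {
  s <- quick_bistable()
  # temporal indicators act on the linearly detrended spatial mean
  ts <- detrend_linear(spatial_mean_series(s))
  expect_equal(ews_indicator(s, "variance", 10)$values,
               rolling_variance(ts, 10)$values)
  # spatial indicators act on spatial-mean-removed snapshots; spatial
  # variance is unchanged by the uniform shift
  tr <- ews_indicator(s, "spatial_variance")
  expect_equal(tr$values,
               apply(s$data, 3, function(m) stats::var(as.vector(m))),
               tolerance = 1e-12)
  expect_identical(tr$window_size, 0L)
  expect_error(ews_indicator(s, "eigen_max"), "window")
  expect_error(ews_indicator(s, "nope", 5), "unknown indicator")
})

test_that("window sweep: grid layout, window-free invariance, degenerate cells", {
  s <- quick_bistable()
  sub <- driver_interval(0, 0.35)
  pcts <- seq(25, 50, length.out = 6)
  g <- window_sensitivity(s, window_pcts = pcts, subset = sub)
  expect_s3_class(g, "sensitivity_grid")
  expect_identical(nrow(g), length(pcts) * 9L)
  # percent-to-points conversion on the 60-snapshot series
  expect_identical(unique(g$W_s[g$indicator == "variance"]),
                   vapply(pcts, window_from_pct, integer(1), T_len = 60))
  # window-free indicators have identical tau across the whole grid
  for (ind in c("spatial_variance", "spatial_skewness",
                "spatial_correlation")) {
    taus <- g$tau[g$indicator == ind]
    expect_identical(length(unique(taus)), 1L)
  }
  # windowed indicators vary with the window
  expect_gt(length(unique(g$tau[g$indicator == "variance"])), 1L)
  # a single window pct degenerates to one trend analysis per indicator
  g1 <- window_sensitivity(s, indicators = c("variance", "spatial_variance"),
                           window_pcts = 30, subset = sub)
  expect_identical(nrow(g1), 2L)
  # a window so large that the subset retains < 10 valid points is marked
  # invalid with a reason, and the sweep continues
  g2 <- window_sensitivity(s, indicators = c("eigen_max"),
                           window_pcts = c(30, 95), subset = sub)
  expect_true(g2$valid[g2$window_pct == 30])
  expect_false(g2$valid[g2$window_pct == 95])
  expect_match(g2$reason[g2$window_pct == 95], "n >= 10|empty selection")
})

test_that("ensemble summaries aggregate tau and significance per cell", {
  s <- quick_bistable()
  sub <- driver_interval(0, 0.35)
  g <- window_sensitivity(s, indicators = c("variance", "spatial_variance"),
                          window_pcts = c(25, 50), subset = sub)
  # identical realisations: sd 0, percent significant 0 or 100
  summ <- ensemble_summary(list(g, g, g))
  expect_s3_class(summ, "assessment_table")
  expect_true(all(summ$sd_tau == 0))
  # cells whose window is viable: percent significant is all-or-nothing for
  # identical realisations; unviable cells (window too large for the
  # subset) aggregate to NA
  ok <- !is.na(summ$pct_significant)
  expect_true(any(ok))
  expect_true(all(summ$pct_significant[ok] %in% c(0, 100)))
  expect_identical(unique(summ$n_realisations), 3L)
  # invariant to realisation ordering
  s2 <- simulate_tipping_data(bistable_model(lattice_n = 10L),
                              sim_config(dt = 0.05, seed = 43,
                                         n_snapshots = 60))
  g2 <- window_sensitivity(s2, indicators = c("variance",
                                              "spatial_variance"),
                           window_pcts = c(25, 50), subset = sub)
  a <- ensemble_summary(list(g, g2))
  b <- ensemble_summary(list(g2, g))
  expect_equal(a$mean_tau, b$mean_tau)
  expect_equal(a$sd_tau, b$sd_tau)
  # single realisation carries its p-value through (where the cell ran)
  one <- ensemble_summary(g)
  expect_false(any(is.na(one$p_value[!is.na(one$mean_tau)])))
  expect_true(all(one$sd_tau == 0))
  # shape mismatch rejected
  g3 <- window_sensitivity(s, indicators = "variance",
                           window_pcts = c(25, 50), subset = sub)
  expect_error(ensemble_summary(list(g, g3)), "mismatch")
  # window-free collapse keeps one row per indicator
  wf <- window_free_table(summ)
  expect_identical(nrow(wf), 1L)
  expect_identical(wf$indicator, "spatial_variance")
})

test_that("trendless indicator ensembles reject at about the nominal rate", {
  # ensemble-level null calibration: iid indicator traces with no trend
  set.seed(99)
  n_rep <- 300
  grids <- lapply(seq_len(n_rep), function(i) {
    tr <- ews_trace(rnorm(50), 1:50, "variance", 0L)
    res <- suppressWarnings(trend_test(tr))
    structure(data.frame(indicator = "variance", window_pct = 25,
                         W_s = 0L, tau = res$tau, z = res$z,
                         p_value = res$p_value,
                         significant = res$significant,
                         n_used = res$n_used, valid = TRUE, reason = "",
                         stringsAsFactors = FALSE),
              class = c("sensitivity_grid", "data.frame"))
  })
  summ <- ensemble_summary(grids)
  expect_gt(summ$pct_significant, 1)
  expect_lt(summ$pct_significant, 11)
  expect_lt(abs(summ$mean_tau), 0.05)
})
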