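test_that("unit conversion uses the 9.8 factor exactly", {
  expect_equal(normalize_units(9.8, "m/s2", "g"), 1.0)
  expect_equal(normalize_units(0, "m/s2", "g"), 0)
  expect_equal(normalize_units(1.0, "g", "m/s2"), 9.8)
  expect_equal(normalize_units(normalize_units(2.5, "g", "m/s2"), "m/s2", "g"), 2.5)
  expect_equal(normalize_units(3, "g", "g"), 3)
  expect_error(normalize_units(1, "g", "ft/s2"), "supported")
})

test_that("index bounds rescale with the sampling-rate ratio", {
  expect_equal(rescale_sample_indices(c(100, 200), 100, 15), c(15L, 30L))
  expect_equal(rescale_sample_indices(c(7, 31), 50, 50), c(7L, 31L))
  expect_equal(rescale_sample_indices(c(10, 33), 100, 15), c(2L, 5L))
  expect_equal(rescale_sample_indices(c(1, 10), 100, 15)[1], 1L)  # floor at 1
})

test_that("grid search selects by exhaustive training criterion", {
  train <- lapply(1:2, function(i) {
    simulate_gait(gait_profile("regular", "wrist", duration_s = 120, seed = 500 + i))
  })
  grid <- list(idle_variance_threshold_g2 = c(0.005, 0.01),
               similarity_tolerance_g = c(0.35, 0.2))
  fit <- grid_search("peak", grid, train, select_tol = 0)
  expect_equal(nrow(fit$scores), 4L)
  # independent re-evaluation of all four cells
  oracle <- apply(expand.grid(grid), 1, function(row) {
    d <- step_detector("peak", peak_params(
      idle_variance_threshold_g2 = row[1], similarity_tolerance_g = row[2]))
    mean(vapply(train, function(tr) {
      truth <- filter_events(tr$events, "steps_only")$time_s
      abs(length(detect_steps(d, tr$recording)) / length(truth) - 1)
    }, numeric(1)))
  })
  expect_equal(fit$scores$criterion, unname(oracle))
  best <- which.min(oracle)
  expect_equal(fit$score, oracle[[best]])
  # the selected parameters are drawn from the grid
  expect_true(fit$params$idle_variance_threshold_g2 %in% grid[[1]])
  expect_true(fit$params$similarity_tolerance_g %in% grid[[2]])
})

test_that("a single-point grid returns that point", {
  train <- list(simulate_gait(gait_profile("regular", "wrist",
                                           duration_s = 60, seed = 77L)))
  fit <- grid_search("autocorr", list(idle_band_g = 0.14), train)
  expect_equal(fit$params$idle_band_g, 0.14)
})

test_that("an exactly-accurate combination is selected over a failing one", {
  series <- pulse_train_series(0.6, 60, 15, amplitude = 0.8)
  truth <- gait_events(pulse_train_centers(0.6, 60),
                       rep("step", length(pulse_train_centers(0.6, 60))))
  train <- list(list(recording = series_recording(series), events = truth))
  # continuity 4 counts every pulse (RCA 1); continuity 200 counts nothing
  fit <- grid_search("peak", list(continuity_count = c(200L, 4L)), train)
  expect_equal(fit$params$continuity_count, 4L)
  expect_equal(fit$score, 0)
})

test_that("degenerate tuning inputs are rejected", {
  expect_error(grid_search("peak", list(continuity_count = 4L), list()), "empty")
  train <- list(simulate_gait(gait_profile("regular", "wrist",
                                           duration_s = 60, seed = 1L)))
  expect_error(grid_search("peak", list(continuity_count = integer(0)), train),
               "non-empty")
})

test_that("tune_detector returns a ready detector with an audit trail", {
  train <- lapply(1:2, function(i) {
    simulate_gait(gait_profile("regular", "wrist", duration_s = 120, seed = 600 + i))
  })
  det <- tune_detector("threshold", train,
                       grid = list(smooth_window_samples = c(3L, 1L),
                                   precision_g = c(0.05, 0.02)))
  expect_s3_class(det, "step_detector")
  expect_false(is.null(det$tuning))
  expect_equal(nrow(det$tuning$scores), 4L)
  expect_lt(det$tuning$score, 0.15)
  d <- detect_steps(det, train[[1]]$recording)
  expect_gt(length(d), 0)
})
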