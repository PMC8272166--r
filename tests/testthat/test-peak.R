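test_that("magnitude is the per-sample Euclidean norm", {
  rec <- accel_recording(c(0, 0.6, 1), c(0, 0.8, 1), c(0, 0, 1), 15, "hip")
  expect_equal(magnitude(rec), c(0, 1, sqrt(3)))
  empty <- accel_recording(numeric(0), numeric(0), numeric(0), 15, "hip")
  expect_error(magnitude(empty), "empty")
})

test_that("find_peaks returns strict local maxima with separation", {
  expect_equal(nrow(find_peaks(1:10)), 0L)
  pk <- find_peaks(c(0, 1, 0, 1, 0), min_separation_samples = 1)
  expect_equal(pk$index, c(2L, 4L))  # spec's 0-based indices 1 and 3
  # separation keeps the larger of two conflicting peaks
  pk2 <- find_peaks(c(0, 1, 0, 2, 0), min_separation_samples = 3)
  expect_equal(pk2$index, 4L)
  expect_equal(nrow(find_peaks(c(1, 2))), 0L)
})

test_that("find_peaks matches an exhaustive local-maxima scan", {
  set.seed(7)
  # noisy sine, period 15 samples, 150 samples: 10 pulses
  t <- 0:149
  s <- sin(2 * pi * t / 15) + stats::rnorm(150, 0, 0.05)
  expect_equal(find_peaks(s, 0)$index, scan_local_maxima(s))
  expect_equal(nrow(find_peaks(s, 8)), 10L)
  # property over random series
  for (i in 1:20) {
    x <- stats::rnorm(80)
    expect_equal(find_peaks(x, 0)$index, scan_local_maxima(x))
  }
})

test_that("motion classification thresholds segment variance with idle ties", {
  params <- peak_params(idle_variance_threshold_g2 = 0.005)
  const <- rep(1, 50)
  pk <- data.frame(index = c(10L, 30L), value = c(1, 1))
  expect_true(all(classify_motion(const, pk, params) == "idle"))

  # a variance exactly at the threshold classifies idle (strict inequality)
  seg <- c(1, 1.1, 1, 1.1, 1, 1.1)
  v <- stats::var(seg)
  no_peaks <- data.frame(index = integer(0), value = numeric(0))
  expect_equal(classify_motion(seg, no_peaks,
    peak_params(idle_variance_threshold_g2 = v)), "idle")
  expect_equal(classify_motion(seg, no_peaks,
    peak_params(idle_variance_threshold_g2 = v - 1e-9)), "walking")

  # simulated walking bouts classify walking between step peaks
  sim <- simulate_gait(gait_profile("regular", "ankle", duration_s = 60, seed = 2L))
  m <- magnitude(sim$recording)
  peaks <- find_peaks(m, 5)
  states <- classify_motion(m, peaks, params)
  mid <- states[10:(length(states) - 10)]  # in-bout segments
  expect_gt(mean(mid == "walking"), 0.95)
})

test_that("the peak gate applies periodicity, similarity and continuity", {
  params <- peak_params(min_peak_interval_s = 0.3, max_peak_interval_s = 1.4,
                        similarity_tolerance_g = 0.35, continuity_count = 4L)
  # zero peaks
  none <- data.frame(index = integer(0), value = numeric(0))
  expect_length(peak_gate(none, "idle", params, 15), 0)
  # 10 evenly spaced similar peaks: all counted (retroactive opening run)
  pk <- data.frame(index = seq(10L, 100L, by = 10L), value = rep(1.8, 10))
  st <- rep("walking", 11)
  expect_length(peak_gate(pk, st, params, 15), 10)
  # 3 valid peaks, a 10 s gap, 3 more: no run reaches 4
  pk2 <- data.frame(index = c(10L, 20L, 30L, 180L, 190L, 200L),
                    value = rep(1.8, 6))
  expect_length(peak_gate(pk2, rep("walking", 7), params, 15), 0)
  # dissimilar magnitudes break the run
  pk3 <- data.frame(index = seq(10L, 100L, by = 10L),
                    value = rep(c(1.8, 1.0), 5))
  expect_length(peak_gate(pk3, rep("walking", 11), params, 15), 0)
})

test_that("peak detection counts every pulse of a periodic train", {
  series <- pulse_train_series(0.6, 30, 15, amplitude = 0.8)
  rec <- series_recording(series)
  det <- detect_steps(step_detector("peak"), rec)
  expect_equal(length(det), 50L)
  # detected times are a subset of peak times
  pk_times <- (find_peaks(series, 5)$index - 1) / 15
  expect_true(all(as.numeric(det) %in% pk_times))
})

test_that("lowering the idle variance threshold never decreases the count", {
  sim <- simulate_gait(gait_profile("unstructured", "hip", duration_s = 120, seed = 6L))
  counts <- vapply(c(0.02, 0.01, 0.005, 0.002, 0.0005), function(v) {
    d <- step_detector("peak", peak_params(idle_variance_threshold_g2 = v))
    length(detect_steps(d, sim$recording))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
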