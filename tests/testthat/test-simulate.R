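test_that("identical seeds give bit-identical recordings and events", {
  p <- gait_profile("semi_regular", "hip", duration_s = 120, seed = 11L)
  a <- simulate_gait(p)
  b <- simulate_gait(p)
  expect_identical(a$recording, b$recording)
  expect_identical(a$events, b$events)
  c <- simulate_gait(gait_profile("semi_regular", "hip", duration_s = 120, seed = 12L))
  expect_false(identical(a$events, c$events))
})

test_that("regular preset realizes the expected step count and composition", {
  sim <- simulate_gait(gait_profile("regular", "ankle", duration_s = 600,
                                    cadence_hz = 1.75, seed = 5L))
  n_steps <- sum(sim$events$label == "step")
  expect_gt(n_steps, 1050 * 0.95)
  expect_lt(n_steps, 1050 * 1.05)
  expect_lt(abs(mean(sim$events$label == "shift") - 0.004), 0.02)
  expect_equal(nrow(sim$recording), 600 * 15)
})

test_that("realized shift fractions are ordered across regimes", {
  fr <- vapply(regimes3, function(rg) {
    sim <- simulate_gait(gait_profile(rg, "hip", duration_s = 600, seed = 3L))
    mean(sim$events$label == "shift")
  }, numeric(1))
  expect_true(fr[["regular"]] < fr[["semi_regular"]])
  expect_true(fr[["semi_regular"]] < fr[["unstructured"]])
})

test_that("a duration too short for any bout yields no events", {
  sim <- simulate_gait(gait_profile("unstructured", "wrist", duration_s = 2,
                                    seed = 1L))
  expect_equal(nrow(sim$events), 0L)
  expect_equal(nrow(sim$recording), 30L)
  # a regime without fidgeting leaves nothing but gravity and sensor noise
  quiet <- simulate_gait(gait_profile("regular", "hip", duration_s = 2, seed = 1L))
  expect_equal(nrow(quiet$events), 0L)
  expect_lt(max(abs(magnitude(quiet$recording) - 1)), 0.2)
})

test_that("invalid profiles are rejected", {
  expect_error(gait_profile(duration_s = 0), "duration_s")
  expect_error(gait_profile(cadence_hz = -1), "cadence_hz")
  expect_error(gait_profile(target_shift_fraction = 1), "target_shift_fraction")
  expect_error(gait_profile(step_amplitude_g = 0.4, shift_amplitude_g = 0.5),
               "smaller")
})

test_that("samples never exceed the sensor range and events are ordered", {
  for (rg in regimes3) {
    sim <- simulate_gait(gait_profile(rg, "ankle", duration_s = 200, seed = 8L))
    m <- as.matrix(sim$recording[, c("x_g", "y_g", "z_g")])
    expect_lte(max(abs(m)), 2)
    expect_true(all(diff(sim$events$time_s) > 0))
  }
})

test_that("in-stride step intervals match the cadence", {
  sim <- simulate_gait(gait_profile("regular", "hip", duration_s = 300,
                                    cadence_hz = 1.75, seed = 2L))
  steps <- sim$events$time_s[sim$events$label == "step"]
  gaps <- diff(steps)
  gaps <- gaps[gaps < 1]  # drop bout boundaries
  expect_lt(abs(stats::median(gaps) - 1 / 1.75), 0.02)
})

test_that("the ankle vertical axis is dominated by the cadence frequency", {
  sim <- simulate_gait(gait_profile("regular", "ankle", duration_s = 300,
                                    cadence_hz = 1.75, seed = 4L))
  z <- sim$recording$z_g
  spec <- Mod(stats::fft(z - mean(z)))[2:(length(z) %/% 2)]
  freqs <- (seq_along(spec)) * 15 / length(z)
  dominant <- freqs[which.max(spec)]
  expect_lt(abs(dominant - 1.75) / 1.75, 0.10)
})

test_that("step impulse waveform honours amplitude, support and periodicity", {
  expect_equal(step_impulse_waveform(0, 2, 15), rep(0, 5))
  w <- step_impulse_waveform(0.8, 2, 15)
  expect_equal(max(w), 0.8)
  expect_lte(length(w), 8)
  expect_error(step_impulse_waveform(0.8, 2, -15), "sample_rate")
  expect_error(step_impulse_waveform(-1, 2, 15), "non-negative")

  # a pulse train's autocorrelation is higher at one period than at half
  train <- pulse_train_series(0.5, 20, 15, amplitude = 0.8)
  lag_full <- round(0.5 * 15)
  lag_half <- round(0.25 * 15)
  ac <- function(l) stats::cor(train[1:(200 - l)], train[(1 + l):200])
  expect_gt(ac(lag_full), ac(lag_half))
})
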