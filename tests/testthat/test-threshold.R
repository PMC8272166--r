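test_that("smoothing is a centered edge-truncated moving average", {
  x <- c(0, 3, 0)
  expect_equal(smooth_signal(x, 1), x)
  expect_equal(smooth_signal(x, 3), c(1.5, 1.0, 1.5))
  expect_error(smooth_signal(x, 0), ">= 1")
  # variance shrinks by roughly the window factor on white noise
  set.seed(1)
  ratios <- replicate(50, {
    z <- stats::rnorm(300)
    stats::var(smooth_signal(z, 5)) / stats::var(z)
  })
  expect_lt(abs(mean(ratios) - 1 / 5), 0.05)
})

test_that("dynamic threshold tracks per-interval extremes", {
  params <- threshold_params(precision_g = 0)
  # constant series: threshold equals the constant after the first boundary
  thr <- dynamic_threshold(rep(0.7, 30), params, 15)
  expect_equal(thr[1:8], rep(1.0, 8))  # global default over the first interval
  expect_equal(thr[9:30], rep(0.7, 22))
  # an interval spanning max 1.4 and min 0.6 yields a 1.0 threshold
  s <- c(rep(c(0.6, 1.4), 4), rep(1, 22))
  thr2 <- dynamic_threshold(s, params, 15)
  expect_equal(thr2[9], 1.0)
})

test_that("dynamic threshold matches a direct per-interval oracle", {
  # oracle: with zero precision, each interval's level is the midpoint of
  # that interval's max and min, applied to the following interval
  set.seed(3)
  t <- (0:149) / 15
  s <- 1 + 0.5 * sin(2 * pi * t) + stats::rnorm(150, 0, 0.02)
  params <- threshold_params(precision_g = 0)
  thr <- dynamic_threshold(s, params, 15)
  starts <- seq(1, 150, by = 8)
  level <- 1.0
  for (k in seq_along(starts)) {
    e <- min(150, starts[k] + 7)
    expect_equal(thr[starts[k]:e], rep(level, e - starts[k] + 1))
    level <- (max(s[starts[k]:e]) + min(s[starts[k]:e])) / 2
  }
  # the precision gate freezes stored extremes against sub-threshold excursions
  params2 <- threshold_params(precision_g = 1.1)
  thr2 <- dynamic_threshold(s, params2, 15)
  for (k in seq_along(starts)[-1])
    expect_equal(thr2[starts[k]], s[starts[k - 1]])  # extremes never updated
})

test_that("only downward crossings emit candidates", {
  expect_length(detect_crossings(rep(1, 20), rep(1, 20), 15), 0)
  t <- (0:29) / 30
  one_cycle <- 1 + sin(2 * pi * t)
  expect_length(detect_crossings(one_cycle, rep(1, 30), 15), 1)
  # 20-cycle sine against a sign-change scan oracle
  tt <- (0:599) / 30
  s <- 1 + sin(2 * pi * tt)
  got <- detect_crossings(s, rep(1, 600), 30)
  oracle <- which(s[-600] > 1 & 1 >= s[-1])
  expect_equal(length(got), 20L)
  expect_equal(got, oracle / 30)
})

test_that("timing regulation enforces the consecutive-run requirement", {
  params <- threshold_params(min_step_interval_s = 0.3, max_step_interval_s = 1.4,
                             consecutive_required = 4L)
  expect_length(regulate_candidates(c(1, 1.5, 2), params), 0)      # 3 < 4
  expect_length(regulate_candidates(c(1, 1.5, 2, 2.5), params), 4) # boundary
  # alternating valid/invalid intervals never build a run of 4
  times <- cumsum(rep(c(0.5, 0.1), 10))
  expect_length(regulate_candidates(times, params), 0)
  # count never exceeds candidates; raising the requirement never helps
  sim <- simulate_gait(gait_profile("semi_regular", "hip", duration_s = 120, seed = 3L))
  m <- magnitude(sim$recording)
  thr <- dynamic_threshold(m, params, 15)
  cand <- detect_crossings(m, thr, 15)
  counts <- vapply(c(1L, 2L, 4L, 8L), function(k) {
    length(regulate_candidates(cand, threshold_params(consecutive_required = k)))
  }, numeric(1))
  expect_lte(counts[1], length(cand))
  expect_true(all(diff(counts) <= 0))
})

test_that("the threshold detector counts every cycle of a pulse train", {
  series <- pulse_train_series(0.6, 30, 15, amplitude = 0.8)
  det <- detect_steps(step_detector("threshold"), series_recording(series))
  expect_equal(length(det), 50L)
})
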