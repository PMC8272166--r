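# Synthetic gait generator: schedules walking bouts and idle pauses, builds
# the ground-truth event list (steps and shifts), then renders a tri-axial
# acceleration signal from impulse templates plus sensor noise.

# Per-position step-impulse attenuation. The ankle sees the sharpest step
# impulses, the hip less, the wrist least (plus arm swing, added below), so
# detection quality is ordered ankle > hip > wrist.
position_scale <- c(wrist = 0.55, hip = 0.8, ankle = 1.0)

# Fidget motion scales the other way round: within-room idle activity
# (reaching, hand work, weight shifts) moves the wrist most and the ankle
# least.
fidget_scale <- c(wrist = 1.0, hip = 0.9, ankle = 0.8)

# Mid-bout shift rate needed so a bout of L steps, 2 boundary shifts and
# L*r interior shifts realizes the target shift fraction f:
#   (2 + L r) / (2 + L r + L) = f
mid_bout_shift_rate <- function(L, f) {
  max(0, (f * (L + 2) - 2) / (L * (1 - f)))
}

#' Simulate a gait recording with ground truth
#'
#' Generates an [accel_recording] and its ground-truth [gait_events] from a
#' [gait_profile]. Walking bouts (lengths drawn from the profile's bout
#' distribution) alternate with idle pauses. Each bout opens and closes with
#' a shift (the first and last steps of a bout, rendered as lower-amplitude
#' impulses); interior pivot/shuffle shifts are inserted at the rate needed
#' to realize the regime's target shift fraction. Every event contributes an
#' impulse to the sensor-local vertical axis (which also carries the +1 g
#' gravity baseline); the unstructured regime additionally fills pauses with
#' aperiodic sub-shift "fidget" impulses that are *not* ground-truth events.
#' Gaussian sensor noise is added per axis and the result is clipped to the
#' +/-2 g sensor range. An event's time is the time of its impulse maximum.
#'
#' The generator is fully deterministic given `profile$seed`.
#'
#' @param profile A [gait_profile].
#' @return An object of class `gait_simulation`: a list with elements
#'   `recording` ([accel_recording]), `events` ([gait_events]) and
#'   `profile`.
#' @export
simulate_gait <- function(profile) {
  if (!inherits(profile, "gait_profile"))
    stop("profile must be a gait_profile", call. = FALSE)
  with_seed(profile$seed, simulate_gait_impl(profile))
}

simulate_gait_impl <- function(p) {
  rate <- p$sample_rate_hz
  period <- 1 / p$cadence_hz
  n <- round(p$duration_s * rate)
  margin <- 0.5  # keep impulses clear of the recording edges

  ev_time <- numeric(0)
  ev_label <- character(0)
  ev_kind <- character(0)
  bout_start <- numeric(0)
  bout_end <- numeric(0)

  t <- stats::runif(1, p$pause_length_s[1], p$pause_length_s[2]) + margin
  repeat {
    L <- sample(seq(p$bout_length_steps[1], p$bout_length_steps[2]), 1L)
    # truncate the final bout so walking can fill the recording
    truncated <- FALSE
    repeat {
      m <- min(L - 1L, round_half_up(L * mid_bout_shift_rate(L, p$target_shift_fraction)))
      n_ev <- L + 2L + m
      # shifts sit outside the repeating pattern: every interval adjacent to
      # a shift is stretched by half a period (see the times loop below)
      bout_dur <- (n_ev + m) * period
      if (t + bout_dur <= p$duration_s - margin || L <= 2L) break
      L <- L - 1L
      truncated <- TRUE
    }
    if (t + bout_dur > p$duration_s - margin) break
    pivot_after <- if (m > 0L) sort(sample(seq_len(L - 1L), m)) else integer(0)

    labels <- "shift"; kinds <- "first_step"
    for (k in seq_len(L)) {
      labels <- c(labels, "step"); kinds <- c(kinds, "in_stride")
      if (k %in% pivot_after) {
        labels <- c(labels, "shift")
        kinds <- c(kinds, sample(c("pivot", "shuffle"), 1L))
      }
    }
    labels <- c(labels, "shift"); kinds <- c(kinds, "last_step")

    # in-stride steps are one period apart; any interval that starts or ends
    # at a shift is stretched by half a period each side (hesitation), so
    # shifts fall outside the repeating pattern
    stride <- kinds == "in_stride"
    mult <- 1 + 0.5 * (!stride[-n_ev]) + 0.5 * (!stride[-1L])
    times <- t + c(0, cumsum(period * mult))

    ev_time <- c(ev_time, times)
    ev_label <- c(ev_label, labels)
    ev_kind <- c(ev_kind, kinds)
    bout_start <- c(bout_start, times[1] - 0.5 * period)
    bout_end <- c(bout_end, times[n_ev] + 0.5 * period)

    if (truncated) break
    t <- times[n_ev] + period +
      stats::runif(1, p$pause_length_s[1], p$pause_length_s[2])
    if (t > p$duration_s - margin) break
  }

  # fidget wiggle fills the idle gaps (unstructured regime): aperiodic
  # broadband bursts of body/hand motion that are not ground-truth events
  fid_time <- numeric(0)
  fid_dur <- numeric(0)
  fid_sd <- numeric(0)
  if (p$fidget_rate_hz > 0) {
    gaps <- idle_gaps(bout_start, bout_end, p$duration_s)
    for (g in seq_len(nrow(gaps))) {
      lo <- gaps$from[g] + margin
      hi <- gaps$to[g] - margin
      tt <- lo
      while (tt < hi) {
        fid_time <- c(fid_time, tt)
        fid_dur <- c(fid_dur, stats::runif(1, 0.3, 0.9))
        fid_sd <- c(fid_sd, stats::runif(1, 0.1, 0.22))
        tt <- tt + (1 / p$fidget_rate_hz) * stats::runif(1, 0.6, 1.6)
      }
    }
  }

  # --- render the signal ---------------------------------------------------
  scale <- position_scale[[p$position]]
  z <- rep(1, n)  # gravity along the sensor-local vertical axis
  x <- numeric(n)
  y <- numeric(n)

  centers <- round_half_up(ev_time * rate) + 1
  for (i in seq_along(ev_time)) {
    if (ev_label[i] == "step") {
      pulse <- step_impulse_waveform(p$step_amplitude_g * scale,
                                     p$cadence_hz, rate)
    } else {
      pulse <- shift_impulse_waveform(ev_kind[i], p$shift_amplitude_g * scale,
                                      p$cadence_hz, rate)
    }
    z <- add_pulse(z, pulse, centers[i])
    x <- add_pulse(x, 0.4 * pulse, centers[i])
  }
  if (length(fid_time)) {
    fcenters <- round_half_up(fid_time * rate) + 1
    fscale <- fidget_scale[[p$position]]
    for (i in seq_along(fid_time)) {
      len <- max(3L, round(fid_dur[i] * rate))
      z <- add_pulse(z, fidget_burst(len, fid_sd[i] * fscale), fcenters[i])
      x <- add_pulse(x, fidget_burst(len, 0.6 * fid_sd[i] * fscale), fcenters[i])
    }
  }

  if (p$position == "wrist" && length(bout_start)) {
    # arm swing at the stride rate (half the step cadence) while walking
    tgrid <- (seq_len(n) - 1) / rate
    walking <- rep(FALSE, n)
    for (b in seq_along(bout_start))
      walking <- walking | (tgrid >= bout_start[b] & tgrid <= bout_end[b])
    swing <- sin(2 * pi * (p$cadence_hz / 2) * tgrid) * walking
    z <- z + 0.12 * swing
    x <- x + 0.15 * swing
  }

  if (p$noise_sd_g > 0) {
    x <- x + stats::rnorm(n, 0, p$noise_sd_g)
    y <- y + stats::rnorm(n, 0, p$noise_sd_g)
    z <- z + stats::rnorm(n, 0, p$noise_sd_g)
  }

  rec <- accel_recording(x, y, z, sample_rate_hz = rate,
                         position = p$position, clip = TRUE)
  structure(list(
    recording = rec,
    events = gait_events(ev_time, ev_label),
    profile = p
  ), class = "gait_simulation")
}

# A burst of low-pass-filtered Gaussian noise with a tapered envelope:
# broadband, aperiodic motion (weight shifts, hand work) that peak- and
# crossing-based counters mistake for steps but that carries no window-to-
# window self-similarity. The 3-sample smoother is rescaled so the burst
# keeps the requested standard deviation.
fidget_burst <- function(len, sd_g) {
  raw <- stats::rnorm(len + 2L, 0, sd_g) * sqrt(3)
  sm <- (raw[1:len] + raw[2:(len + 1L)] + raw[3:(len + 2L)]) / 3
  sm * sin(pi * (seq_len(len) - 0.5) / len)  # taper to zero at the edges
}

# Complement of the bout intervals within [0, duration].
idle_gaps <- function(bout_start, bout_end, duration) {
  if (!length(bout_start))
    return(data.frame(from = 0, to = duration))
  data.frame(
    from = c(0, bout_end),
    to = c(bout_start, duration)
  )
}

#' @export
print.gait_simulation <- function(x, ...) {
  ns <- sum(x$events$label == "step")
  nh <- sum(x$events$label == "shift")
  frac <- if (nrow(x$events)) nh / nrow(x$events) else NA_real_
  cat(sprintf(
    "<gait_simulation> %s gait at the %s: %d steps + %d shifts (%.1f%% shifts)\n",
    x$profile$regime, x$profile$position, ns, nh, 100 * frac
  ))
  print(x$recording)
  invisible(x)
}
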