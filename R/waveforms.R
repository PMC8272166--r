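#' Step impulse waveform
#'
#' The elementary pulse the gait simulator superimposes on the vertical axis
#' for each step: a sampled half-sine on a zero baseline whose maximum
#' equals `amplitude_g` and whose support is at most one step period
#' (`1 / cadence_hz` seconds). A real step produces one dominant peak in the
#' acceleration signal per step; this pulse is the simplest shape with that
#' property.
#'
#' @param amplitude_g Peak acceleration of the pulse in g (>= 0; 0 yields an
#'   all-zero waveform).
#' @param cadence_hz Step rate in Hz; bounds the pulse support.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @return Numeric vector of samples; odd length, so the peak falls exactly
#'   on the middle sample.
#' @export
step_impulse_waveform <- function(amplitude_g, cadence_hz, sample_rate_hz) {
  if (!is.numeric(amplitude_g) || amplitude_g < 0)
    stop("amplitude_g must be non-negative", call. = FALSE)
  stopifnot_scalar(cadence_hz, "cadence_hz", positive = TRUE)
  stopifnot_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  # support 0.7 of a step period, forced odd so the peak is an exact sample
  n <- floor(0.7 * sample_rate_hz / cadence_hz)
  n <- max(3L, if (n %% 2L == 0L) n - 1L else n)
  if (n > 1 + sample_rate_hz / cadence_hz) n <- n - 2L  # keep support <= period
  amplitude_g * sin(pi * (seq_len(n) - 1) / (n - 1))
}

# Shift impulse templates (internal). Four shapes observed at bout
# boundaries and during irregular motion: the first and last steps of a bout
# (smaller, skewed pulses), pivots (biphasic) and shuffles (double bump).
# Every template has maximum exactly `amplitude_g`.
shift_impulse_waveform <- function(kind = c("first_step", "last_step",
                                            "pivot", "shuffle"),
                                   amplitude_g, cadence_hz, sample_rate_hz) {
  kind <- match.arg(kind)
  n <- max(5L, floor(0.9 * sample_rate_hz / cadence_hz))
  if (n %% 2L == 0L) n <- n + 1L
  u <- (seq_len(n) - 1) / (n - 1)
  w <- switch(kind,
    first_step = u * sin(pi * u),          # rising emphasis
    last_step  = (1 - u) * sin(pi * u),    # falling emphasis
    pivot      = sin(2 * pi * u),          # biphasic lobe
    shuffle    = abs(sin(2 * pi * u))      # two small bumps
  )
  amplitude_g * w / max(abs(w))
}

# Add a pulse to `signal` with its own peak aligned to sample `center`
# (1-based); out-of-range samples are dropped.
add_pulse <- function(signal, pulse, center) {
  peak_at <- which.max(abs(pulse))
  idx <- center - peak_at + seq_along(pulse)
  keep <- idx >= 1L & idx <= length(signal)
  signal[idx[keep]] <- signal[idx[keep]] + pulse[keep]
  signal
}
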