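#' Gait simulation profile
#'
#' Describes the gait regime, sensor position and signal parameters for one
#' simulated recording. The three regimes model the consistency-of-gait
#' spectrum seen in everyday activities:
#'
#' * `regular` — long uninterrupted walking bouts (exercise-like); shifts
#'   are essentially only the first/last steps of the few bouts, about 0.4%
#'   of all events.
#' * `semi_regular` — walking through a building: bouts of tens of steps
#'   broken by stops, doors and turns; about 17.1% of events are shifts.
#' * `unstructured` — within-room activity: very brief bouts of roughly
#'   3–10 steps separated by long idle periods with non-step fidgeting;
#'   about 35.4% of events are shifts.
#'
#' Defaults reflect the benchmark conditions: 15 Hz sampling at a +/-2 g
#' range, 10-minute recordings, and a walking cadence of 1.75 steps/s
#' (about 1050 steps over 10 minutes of continuous walking). Sensor
#' position scales the step-impulse signal-to-noise ratio (ankle highest,
#' wrist lowest) and the wrist additionally carries an arm-swing sinusoid
#' at the stride rate.
#'
#' @param regime Gait regime preset.
#' @param position Sensor body position.
#' @param duration_s Recording length in seconds (> 0).
#' @param cadence_hz Step rate during walking bouts, steps/s (> 0).
#' @param step_amplitude_g Peak step-impulse acceleration, g.
#' @param shift_amplitude_g Peak shift-impulse acceleration, g; must be
#'   smaller than `step_amplitude_g` (boundary steps produce smaller
#'   accelerations than in-stride steps).
#' @param bout_length_steps Length-2 integer vector `(min, max)` of
#'   consecutive steps per walking bout; defaults per regime.
#' @param pause_length_s Length-2 numeric `(min, max)` of idle gap between
#'   bouts in seconds; defaults per regime.
#' @param target_shift_fraction Fraction of all events that are shifts, in
#'   \[0, 1); defaults per regime (0.004 / 0.171 / 0.354).
#' @param noise_sd_g Additive Gaussian sensor noise SD, g.
#' @param fidget_rate_hz Mean rate of sub-shift idle wiggle impulses during
#'   pauses (unstructured regime only; 0 elsewhere).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return An object of class `gait_profile`.
#' @seealso [simulate_gait()]
#' @export
gait_profile <- function(regime = c("regular", "semi_regular", "unstructured"),
                         position = c("wrist", "hip", "ankle"),
                         duration_s = 600,
                         cadence_hz = 1.75,
                         step_amplitude_g = 0.8,
                         shift_amplitude_g = 0.4,
                         bout_length_steps = NULL,
                         pause_length_s = NULL,
                         target_shift_fraction = NULL,
                         noise_sd_g = 0.03,
                         fidget_rate_hz = NULL,
                         sample_rate_hz = 15,
                         seed = 1L) {
  regime <- match.arg(regime)
  position <- match.arg(position)
  preset <- switch(regime,
    regular       = list(shift = 0.004, bout = c(400L, 700L), pause = c(1, 3),   fidget = 0),
    semi_regular  = list(shift = 0.171, bout = c(15L, 40L),   pause = c(2, 9),   fidget = 0),
    unstructured  = list(shift = 0.354, bout = c(3L, 10L),    pause = c(8, 24),  fidget = 1.2)
  )
  if (is.null(bout_length_steps)) bout_length_steps <- preset$bout
  if (is.null(pause_length_s)) pause_length_s <- preset$pause
  if (is.null(target_shift_fraction)) target_shift_fraction <- preset$shift
  if (is.null(fidget_rate_hz)) fidget_rate_hz <- preset$fidget

  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(cadence_hz, "cadence_hz", positive = TRUE)
  stopifnot_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  if (target_shift_fraction < 0 || target_shift_fraction >= 1)
    stop("target_shift_fraction must be in [0, 1)", call. = FALSE)
  if (shift_amplitude_g >= step_amplitude_g)
    stop("shift_amplitude_g must be smaller than step_amplitude_g",
         call. = FALSE)
  if (length(bout_length_steps) != 2L || bout_length_steps[1] > bout_length_steps[2] ||
      bout_length_steps[1] < 1)
    stop("bout_length_steps must be (min, max) with 1 <= min <= max",
         call. = FALSE)
  if (length(pause_length_s) != 2L || pause_length_s[1] > pause_length_s[2] ||
      pause_length_s[1] < 0)
    stop("pause_length_s must be (min, max) with 0 <= min <= max",
         call. = FALSE)

  structure(list(
    regime = regime, position = position,
    duration_s = duration_s, cadence_hz = cadence_hz,
    step_amplitude_g = step_amplitude_g, shift_amplitude_g = shift_amplitude_g,
    bout_length_steps = as.integer(bout_length_steps),
    pause_length_s = as.numeric(pause_length_s),
    target_shift_fraction = target_shift_fraction,
    noise_sd_g = noise_sd_g, fidget_rate_hz = fidget_rate_hz,
    sample_rate_hz = sample_rate_hz, seed = as.integer(seed)
  ), class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<gait_profile> %s gait, %s sensor, %g s @ %g Hz\n",
           "  cadence %g steps/s, step %.2f g / shift %.2f g, ",
           "target shift fraction %.1f%%, seed %d\n"),
    x$regime, x$position, x$duration_s, x$sample_rate_hz,
    x$cadence_hz, x$step_amplitude_g, x$shift_amplitude_g,
    100 * x$target_shift_fraction, x$seed
  ))
  invisible(x)
}
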