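#' Tri-axial accelerometer recording
#'
#' An `accel_recording` holds a uniformly sampled tri-axial acceleration
#' signal in gravities (g), together with its sampling rate and the body
#' position the sensor was worn at. Sample `i` (1-based) is at time
#' `start_time_s + (i - 1) / sample_rate_hz`. All components are clipped to
#' the sensor range of \[-2, +2\] g, matching low-power wearable
#' accelerometers configured at a +/-2 g range.
#'
#' @param x,y,z Numeric vectors of equal length: acceleration per axis, in g.
#' @param sample_rate_hz Sampling rate in Hz (default 15).
#' @param position Body position tag: `"wrist"`, `"hip"` or `"ankle"`.
#' @param start_time_s Time origin in seconds (default 0).
#' @param clip Clip components to \[-2, 2\] g (default `TRUE`).
#'
#' @return An object of class `accel_recording`: a data frame with columns
#'   `time_s`, `x_g`, `y_g`, `z_g` and attributes `sample_rate_hz`,
#'   `position`, `start_time_s`.
#' @export
accel_recording <- function(x, y, z, sample_rate_hz = 15,
                            position = c("wrist", "hip", "ankle"),
                            start_time_s = 0, clip = TRUE) {
  position <- match.arg(position)
  stopifnot_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length", call. = FALSE)
  if (clip) {
    x <- pmin(pmax(x, -2), 2)
    y <- pmin(pmax(y, -2), 2)
    z <- pmin(pmax(z, -2), 2)
  }
  rec <- data.frame(
    time_s = start_time_s + (seq_len(n) - 1) / sample_rate_hz,
    x_g = x, y_g = y, z_g = z
  )
  structure(rec,
    sample_rate_hz = sample_rate_hz,
    position = position,
    start_time_s = start_time_s,
    class = c("accel_recording", "data.frame")
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  rate <- attr(x, "sample_rate_hz")
  cat(sprintf(
    "<accel_recording> %d samples @ %g Hz (%.1f s), position: %s\n",
    nrow(x), rate, nrow(x) / rate, attr(x, "position")
  ))
  if (nrow(x)) {
    m <- magnitude(x)
    cat(sprintf("  magnitude: median %.3f g, range [%.3f, %.3f] g\n",
                stats::median(m), min(m), max(m)))
  }
  invisible(x)
}

#' @export
plot.accel_recording <- function(x, which = c("magnitude", "axes"), ...) {
  which <- match.arg(which)
  if (which == "magnitude") {
    graphics::plot(x$time_s, magnitude(x), type = "l",
                   xlab = "time (s)", ylab = "|a| (g)", ...)
  } else {
    graphics::matplot(x$time_s, cbind(x$x_g, x$y_g, x$z_g), type = "l",
                      lty = 1, xlab = "time (s)", ylab = "acceleration (g)",
                      ...)
    graphics::legend("topright", legend = c("x", "y", "z"),
                     col = 1:3, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Acceleration magnitude
#'
#' Per-sample Euclidean norm of the three axes,
#' `sqrt(x^2 + y^2 + z^2)`, in gravities. At rest the magnitude idles near
#' 1 g; step impulses appear as excursions above it.
#'
#' @param recording An [accel_recording], or a data frame with columns
#'   `x_g`, `y_g`, `z_g`.
#' @return Numeric vector of the same length as the recording.
#' @export
magnitude <- function(recording) {
  if (nrow(recording) == 0L)
    stop("recording is empty", call. = FALSE)
  sqrt(recording$x_g^2 + recording$y_g^2 + recording$z_g^2)
}

#' Read an accelerometer recording from CSV
#'
#' Expects a header row and four columns: time in seconds plus X/Y/Z
#' acceleration in gravities. Timestamps must be strictly increasing. If the
#' timestamps deviate from a uniform grid by more than 1% of the nominal
#' period, the signal is resampled onto the nominal rate by linear
#' interpolation. Values are asserted to be in gravities: any component with
#' absolute value above 8 raises an error suggesting the input is in m/s^2
#' (divide by 9.8 to convert).
#'
#' @param path CSV file path.
#' @param sample_rate_hz Nominal sampling rate; if `NULL`, estimated as the
#'   reciprocal of the median timestamp difference.
#' @param position Body position tag to attach.
#' @return An [accel_recording].
#' @export
read_recording <- function(path, sample_rate_hz = NULL,
                           position = c("wrist", "hip", "ankle")) {
  position <- match.arg(position)
  df <- utils::read.csv(path)
  if (ncol(df) < 4L)
    stop("recording CSV must have time plus three acceleration columns",
         call. = FALSE)
  tm <- as.numeric(df[[1L]])
  ax <- as.numeric(df[[2L]]); ay <- as.numeric(df[[3L]]); az <- as.numeric(df[[4L]])
  if (anyNA(tm) || anyNA(ax) || anyNA(ay) || anyNA(az))
    stop("malformed recording CSV: non-numeric values", call. = FALSE)
  if (length(tm) > 1L && any(diff(tm) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (max(abs(c(ax, ay, az))) > 8)
    stop(paste0(
      "acceleration values exceed 8: input looks like m/s^2, not gravities; ",
      "divide by 9.8 to convert to g"
    ), call. = FALSE)
  if (is.null(sample_rate_hz)) {
    if (length(tm) < 2L)
      stop("cannot infer sample rate from fewer than 2 samples", call. = FALSE)
    sample_rate_hz <- 1 / stats::median(diff(tm))
  }
  period <- 1 / sample_rate_hz
  n <- length(tm)
  grid <- tm[1L] + (seq_len(n) - 1) * period
  if (n > 1L && max(abs(tm - grid)) > 0.01 * period) {
    # resample by linear interpolation onto the nominal grid
    grid <- seq(tm[1L], tm[n], by = period)
    ax <- stats::approx(tm, ax, xout = grid)$y
    ay <- stats::approx(tm, ay, xout = grid)$y
    az <- stats::approx(tm, az, xout = grid)$y
  }
  accel_recording(ax, ay, az, sample_rate_hz = sample_rate_hz,
                  position = position, start_time_s = tm[1L], clip = FALSE)
}

#' Write an accelerometer recording to CSV
#'
#' Writes `time_s,x_g,y_g,z_g` with 6-decimal floats; [read_recording] on
#' the result round-trips losslessly to that precision.
#'
#' @param recording An [accel_recording].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  out <- data.frame(
    time_s = sprintf("%.6f", recording$time_s),
    x_g = sprintf("%.6f", recording$x_g),
    y_g = sprintf("%.6f", recording$y_g),
    z_g = sprintf("%.6f", recording$z_g)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
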