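# Peak-detection step counter: magnitude -> peaks -> idle/walking motion
# state -> periodicity / similarity / continuity gating.

#' Peak-detector parameters
#'
#' @param idle_variance_threshold_g2 Variance of the magnitude signal below
#'   (or equal to) which an inter-peak segment is classified idle, in g^2.
#' @param min_peak_interval_s,max_peak_interval_s Periodicity bounds: a peak
#'   is only a valid step candidate if its interval to the previous
#'   candidate lies in this range, seconds.
#' @param similarity_tolerance_g Maximum absolute difference between
#'   consecutive accepted peak magnitudes, g.
#' @param continuity_count Number of consecutive valid peaks required before
#'   a run is counted (the whole run, including its opening peaks, is then
#'   counted retroactively).
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(idle_variance_threshold_g2 = 0.005,
                        min_peak_interval_s = 0.3,
                        max_peak_interval_s = 1.4,
                        similarity_tolerance_g = 0.35,
                        continuity_count = 4L) {
  if (min_peak_interval_s <= 0 || min_peak_interval_s >= max_peak_interval_s)
    stop("need 0 < min_peak_interval_s < max_peak_interval_s", call. = FALSE)
  if (continuity_count < 1) stop("continuity_count must be >= 1", call. = FALSE)
  if (similarity_tolerance_g <= 0)
    stop("similarity_tolerance_g must be positive", call. = FALSE)
  structure(list(
    idle_variance_threshold_g2 = idle_variance_threshold_g2,
    min_peak_interval_s = min_peak_interval_s,
    max_peak_interval_s = max_peak_interval_s,
    similarity_tolerance_g = similarity_tolerance_g,
    continuity_count = as.integer(continuity_count)
  ), class = "peak_params")
}

#' Find local maxima with a minimum separation
#'
#' Returns strict local maxima of a series; where two maxima fall closer
#' than `min_separation_samples`, the larger is kept (ties keep the earlier
#' one). Series shorter than 3 samples have no interior maxima.
#'
#' @param series Numeric vector.
#' @param min_separation_samples Minimum index spacing between returned
#'   peaks (0 disables the separation constraint).
#' @return Data frame with columns `index` (strictly increasing) and
#'   `value`.
#' @export
find_peaks <- function(series, min_separation_samples = 0) {
  n <- length(series)
  if (n < 3L)
    return(data.frame(index = integer(0), value = numeric(0)))
  core <- series[2:(n - 1)]
  idx <- which(core > series[1:(n - 2)] & core > series[3:n]) + 1L
  if (length(idx) && min_separation_samples > 0) {
    ord <- idx[order(-series[idx], idx)]  # by value desc, then earlier index
    keep <- integer(0)
    for (i in ord) {
      if (!length(keep) || all(abs(keep - i) >= min_separation_samples))
        keep <- c(keep, i)
    }
    idx <- sort(keep)
  }
  data.frame(index = idx, value = series[idx])
}

#' Classify motion state between peaks
#'
#' Splits the series at the peak indices and labels each segment `walking`
#' if its sample variance exceeds the idle threshold, else `idle` (a
#' variance exactly equal to the threshold is idle). Segments include the
#' stretch before the first peak and after the last, so `n_peaks + 1`
#' states are returned; state `i` describes the segment *preceding* peak
#' `i`.
#'
#' @param series Numeric magnitude series.
#' @param peaks Data frame from [find_peaks()].
#' @param params A [peak_params] object.
#' @return Character vector of length `nrow(peaks) + 1`.
#' @export
classify_motion <- function(series, peaks, params) {
  bounds <- c(1L, peaks$index, length(series))
  vapply(seq_len(length(bounds) - 1L), function(i) {
    seg <- series[bounds[i]:bounds[i + 1L]]
    v <- if (length(seg) > 1L) stats::var(seg) else 0
    if (v > params$idle_variance_threshold_g2) "walking" else "idle"
  }, character(1))
}

#' Gate peaks into counted steps
#'
#' A peak is a valid step candidate iff its preceding segment is walking,
#' its interval to the previous candidate in the current run lies within
#' the periodicity bounds, and its magnitude is within the similarity
#' tolerance of the previous accepted peak. Runs of consecutive valid
#' candidates are counted only once they reach `continuity_count`, at which
#' point the entire run (including its opening peaks) is counted and
#' counting continues while validity persists. Step times are peak times in
#' seconds.
#'
#' @param peaks Data frame from [find_peaks()].
#' @param states Character vector from [classify_motion()].
#' @param params A [peak_params] object.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Sorted numeric vector of detected step times (seconds).
#' @export
peak_gate <- function(peaks, states, params, sample_rate_hz) {
  k <- nrow(peaks)
  if (k == 0L) return(numeric(0))
  if (length(states) < k)
    stop("states must cover every peak", call. = FALSE)
  counted <- logical(k)
  chain <- integer(0)
  flush <- function(chain) {
    if (length(chain) >= params$continuity_count) counted[chain] <<- TRUE
  }
  for (i in seq_len(k)) {
    if (states[i] != "walking") {
      flush(chain); chain <- integer(0); next
    }
    if (length(chain)) {
      prev <- chain[length(chain)]
      dt <- (peaks$index[i] - peaks$index[prev]) / sample_rate_hz
      ok <- dt >= params$min_peak_interval_s &&
        dt <= params$max_peak_interval_s &&
        abs(peaks$value[i] - peaks$value[prev]) <= params$similarity_tolerance_g
      if (ok) chain <- c(chain, i) else { flush(chain); chain <- i }
    } else {
      chain <- i
    }
  }
  flush(chain)
  (peaks$index[counted] - 1) / sample_rate_hz
}

detect_peak <- function(recording, params) {
  rate <- attr(recording, "sample_rate_hz")
  m <- magnitude(recording)
  peaks <- find_peaks(m, ceiling(params$min_peak_interval_s * rate))
  states <- classify_motion(m, peaks, params)
  peak_gate(peaks, states, params, rate)
}
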