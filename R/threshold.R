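# Dynamic-threshold crossing step counter: smoothing -> adaptive crossing
# level (midpoint of windowed max/min) -> negative-slope crossings ->
# inter-step timing regulation with a consecutive-run requirement.

#' Threshold-detector parameters
#'
#' @param smooth_window_samples Centered moving-average width in samples
#'   (1 = no smoothing).
#' @param threshold_update_interval_s Seconds between recomputations of the
#'   crossing level (default 0.5 s).
#' @param precision_g Minimum excursion beyond the stored extreme required
#'   to update the stored max/min within an interval, g.
#' @param min_step_interval_s,max_step_interval_s Valid inter-step timing
#'   bounds, seconds.
#' @param consecutive_required Candidate steps needed in a run before the
#'   run is accepted (default 4); the whole run is then counted.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(smooth_window_samples = 3L,
                             threshold_update_interval_s = 0.5,
                             precision_g = 0.05,
                             min_step_interval_s = 0.3,
                             max_step_interval_s = 1.4,
                             consecutive_required = 4L) {
  if (smooth_window_samples < 1) stop("smooth_window_samples must be >= 1", call. = FALSE)
  if (precision_g < 0) stop("precision_g must be >= 0", call. = FALSE)
  if (min_step_interval_s <= 0 || min_step_interval_s >= max_step_interval_s)
    stop("need 0 < min_step_interval_s < max_step_interval_s", call. = FALSE)
  if (consecutive_required < 1) stop("consecutive_required must be >= 1", call. = FALSE)
  structure(list(
    smooth_window_samples = as.integer(smooth_window_samples),
    threshold_update_interval_s = threshold_update_interval_s,
    precision_g = precision_g,
    min_step_interval_s = min_step_interval_s,
    max_step_interval_s = max_step_interval_s,
    consecutive_required = as.integer(consecutive_required)
  ), class = "threshold_params")
}

#' Centered moving-average smoother
#'
#' Edge windows are truncated to the available samples, so the output has
#' the same length as the input and `window = 1` is the identity.
#'
#' @param series Numeric vector.
#' @param window Window width in samples (>= 1).
#' @return Smoothed numeric vector.
#' @export
smooth_signal <- function(series, window) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (window == 1 || length(series) <= 1L) return(series)
  as.numeric(zoo::rollapply(zoo::zoo(series), width = window, FUN = mean,
                            partial = TRUE, align = "center"))
}

#' Dynamic crossing threshold
#'
#' Within each consecutive interval of `threshold_update_interval_s`, track
#' a running max and min of the series (initialized at the interval's first
#' sample), updating a stored extreme only when a candidate exceeds it by
#' more than `precision_g`. At each interval boundary the crossing level
#' becomes `(stored_max + stored_min) / 2` and is held constant until the
#' next boundary. The first interval uses the default level of 1.0 g (the
#' resting magnitude).
#'
#' @param series Numeric magnitude series (non-empty).
#' @param params A [threshold_params] object.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Numeric vector of per-sample crossing levels, same length as
#'   `series`.
#' @export
dynamic_threshold <- function(series, params, sample_rate_hz) {
  n <- length(series)
  if (n == 0L) stop("series is empty", call. = FALSE)
  ival <- max(1L, round(params$threshold_update_interval_s * sample_rate_hz))
  thr <- numeric(n)
  level <- 1.0
  starts <- seq(1L, n, by = ival)
  for (s in starts) {
    e <- min(n, s + ival - 1L)
    thr[s:e] <- level
    smax <- series[s]
    smin <- series[s]
    if (e > s) {
      for (j in (s + 1L):e) {
        if (series[j] > smax + params$precision_g) smax <- series[j]
        if (series[j] < smin - params$precision_g) smin <- series[j]
      }
    }
    level <- (smax + smin) / 2
  }
  thr
}

#' Detect downward threshold crossings
#'
#' Emits a step candidate at sample `i` whenever the series crosses its
#' threshold in the downward direction between samples `i - 1` and `i`,
#' i.e. `series[i-1] > thr[i] >= series[i]` (negative slope at the
#' crossing). Upward crossings are ignored.
#'
#' @param series,thresholds Numeric vectors of equal length.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Sorted numeric vector of candidate times (seconds).
#' @export
detect_crossings <- function(series, thresholds, sample_rate_hz) {
  n <- length(series)
  if (length(thresholds) != n)
    stop("series and thresholds must have equal length", call. = FALSE)
  if (n < 2L) return(numeric(0))
  prev <- series[1:(n - 1)]
  curr <- series[2:n]
  th <- thresholds[2:n]
  idx <- which(prev > th & th >= curr) + 1L
  (idx - 1) / sample_rate_hz
}

#' Regulate candidate steps by timing and continuity
#'
#' A candidate is valid iff its interval to the previous candidate lies in
#' `[min_step_interval_s, max_step_interval_s]`. A run counter tracks
#' consecutive valid candidates; once it reaches `consecutive_required` the
#' entire run is counted retroactively and counting continues while
#' validity persists. An invalid interval resets the counter (the
#' offending candidate starts a new potential run).
#'
#' @param candidates Sorted numeric vector of candidate times (seconds).
#' @param params A [threshold_params] object.
#' @return Sorted numeric vector of counted step times (seconds).
#' @export
regulate_candidates <- function(candidates, params) {
  k <- length(candidates)
  if (k == 0L) return(numeric(0))
  counted <- logical(k)
  chain <- 1L
  flush <- function(chain) {
    if (length(chain) >= params$consecutive_required) counted[chain] <<- TRUE
  }
  for (i in seq_len(k)[-1]) {
    dt <- candidates[i] - candidates[chain[length(chain)]]
    if (dt >= params$min_step_interval_s && dt <= params$max_step_interval_s) {
      chain <- c(chain, i)
    } else {
      flush(chain); chain <- i
    }
  }
  flush(chain)
  candidates[counted]
}

detect_threshold <- function(recording, params) {
  rate <- attr(recording, "sample_rate_hz")
  m <- smooth_signal(magnitude(recording), params$smooth_window_samples)
  thr <- dynamic_threshold(m, params, rate)
  cand <- detect_crossings(m, thr, rate)
  regulate_candidates(cand, params)
}
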