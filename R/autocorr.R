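# Adaptive-window normalized-autocorrelation step counter: search for the
# lag (candidate step period) maximizing the similarity between adjacent
# windows, reject idle segments, threshold the autocorrelation score, and
# emit steps at one per optimal lag.

#' Autocorrelation-detector parameters
#'
#' @param min_window_s,max_window_s Bounds of the candidate step-period
#'   search, seconds. The window models a single step period, so the bounds
#'   should bracket plausible walking cadences (defaults 0.35–1.0 s, i.e.
#'   1–2.9 steps/s).
#' @param search_halfwidth_samples Half-width, in samples, of the refined
#'   lag search around the previous optimum once one is known.
#' @param autocorr_threshold Minimum normalized autocorrelation score (in
#'   \[-1, 1\]) for a segment to count as walking.
#' @param idle_band_g A segment whose magnitude standard deviation is
#'   strictly below this value is idle and emits nothing, g.
#' @return An object of class `autocorr_params`.
#' @export
autocorr_params <- function(min_window_s = 0.35,
                            max_window_s = 1.0,
                            search_halfwidth_samples = 3L,
                            autocorr_threshold = 0.7,
                            idle_band_g = 0.14) {
  if (min_window_s <= 0 || min_window_s >= max_window_s)
    stop("need 0 < min_window_s < max_window_s", call. = FALSE)
  if (autocorr_threshold < -1 || autocorr_threshold > 1)
    stop("autocorr_threshold must be in [-1, 1]", call. = FALSE)
  if (idle_band_g < 0) stop("idle_band_g must be >= 0", call. = FALSE)
  structure(list(
    min_window_s = min_window_s, max_window_s = max_window_s,
    search_halfwidth_samples = as.integer(search_halfwidth_samples),
    autocorr_threshold = autocorr_threshold,
    idle_band_g = idle_band_g
  ), class = "autocorr_params")
}

#' Normalized autocorrelation between adjacent windows
#'
#' Pearson-style similarity between the window `A` of `lag_samples` samples
#' starting at `start_index` and its immediate successor `B` of the same
#' length: each window is mean-centered and the cross-product is divided by
#' the product of the window standard deviations and the lag, yielding a
#' score in \[-1, 1\]. A window with zero variance yields score 0.
#'
#' @param series Numeric vector.
#' @param start_index 1-based start of the first window.
#' @param lag_samples Window length in samples (>= 2).
#' @return Score in \[-1, 1\].
#' @export
normalized_autocorr <- function(series, start_index, lag_samples) {
  lag_samples <- as.integer(lag_samples)
  if (lag_samples < 2L) stop("lag_samples must be >= 2", call. = FALSE)
  if (start_index < 1L || start_index + 2L * lag_samples - 1L > length(series))
    stop("window out of bounds", call. = FALSE)
  a <- series[start_index:(start_index + lag_samples - 1L)]
  b <- series[(start_index + lag_samples):(start_index + 2L * lag_samples - 1L)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Search for the optimal window size
#'
#' Scans candidate lags and returns the one maximizing the normalized
#' autocorrelation at `start_index`. With no previous optimum the full
#' range `[min_window_s, max_window_s]` (in samples) is scanned; otherwise
#' the search is confined to `previous_optimum +/-
#' search_halfwidth_samples`, clamped to the full range. Ties break toward
#' the smaller lag. Lags that would run past the end of the series are
#' skipped; if none fit, `NULL` is returned to signal end of signal.
#'
#' @param series Numeric vector.
#' @param start_index 1-based window start.
#' @param params An [autocorr_params] object.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param previous_optimum Previously selected lag in samples, or `NULL`.
#' @return `list(lag_samples, score)`, or `NULL` at end of signal.
#' @export
find_optimal_window <- function(series, start_index, params, sample_rate_hz,
                                previous_optimum = NULL) {
  lo <- max(2L, round(params$min_window_s * sample_rate_hz))
  hi <- max(lo, round(params$max_window_s * sample_rate_hz))
  if (!is.null(previous_optimum)) {
    lo2 <- max(lo, previous_optimum - params$search_halfwidth_samples)
    hi2 <- min(hi, previous_optimum + params$search_halfwidth_samples)
    lo <- lo2; hi <- max(lo2, hi2)
  }
  lags <- lo:hi
  lags <- lags[start_index + 2L * lags - 1L <= length(series)]
  if (!length(lags)) return(NULL)
  scores <- vapply(lags, function(l) normalized_autocorr(series, start_index, l),
                   numeric(1))
  best <- which.max(scores)  # first maximum = smallest lag on ties
  list(lag_samples = lags[best], score = scores[best])
}

#' Idle check for a magnitude segment
#'
#' A segment is idle iff its sample standard deviation is strictly below
#' `idle_band_g`; at rest the magnitude stays near 1 g with only sensor
#' noise, while any stepping adds substantial spread.
#'
#' @param series_segment Non-empty numeric vector.
#' @param params An [autocorr_params] object.
#' @return Logical scalar.
#' @export
is_idle <- function(series_segment, params) {
  if (!length(series_segment)) stop("segment is empty", call. = FALSE)
  s <- if (length(series_segment) > 1L) stats::sd(series_segment) else 0
  s < params$idle_band_g
}

detect_autocorr <- function(recording, params) {
  rate <- attr(recording, "sample_rate_hz")
  m <- magnitude(recording)
  n <- length(m)
  pos <- 1L
  prev <- NULL
  times <- numeric(0)
  repeat {
    best <- find_optimal_window(m, pos, params, rate, previous_optimum = prev)
    if (is.null(best)) break
    lag <- best$lag_samples
    seg <- m[pos:(pos + 2L * lag - 1L)]
    if (!is_idle(seg, params) && best$score > params$autocorr_threshold) {
      # one step per optimal window; place it at the window boundary
      times <- c(times, (pos - 1L + lag) / rate)
      prev <- lag
    } else {
      prev <- NULL  # lost lock: next search scans the full range
    }
    pos <- pos + lag
  }
  times
}
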