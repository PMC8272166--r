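#' Construct a step detector
#'
#' Bundles one of the three detector families with its parameters into a
#' `step_detector` object that can be applied to recordings with
#' [detect_steps()] (or `predict()`).
#'
#' @param algorithm `"peak"`, `"threshold"` or `"autocorr"`.
#' @param params A [peak_params], [threshold_params] or [autocorr_params]
#'   object matching `algorithm`; defaults to that family's defaults.
#' @return An object of class `c("<algorithm>_step_detector",
#'   "step_detector")`.
#' @export
step_detector <- function(algorithm = c("peak", "threshold", "autocorr"),
                          params = NULL) {
  algorithm <- match.arg(algorithm)
  expected <- paste0(algorithm, "_params")
  if (is.null(params))
    params <- switch(algorithm,
      peak = peak_params(),
      threshold = threshold_params(),
      autocorr = autocorr_params()
    )
  if (!inherits(params, expected))
    stop(sprintf("params must be a %s object", expected), call. = FALSE)
  structure(
    list(algorithm = algorithm, params = params, tuning = NULL),
    class = c(paste0(algorithm, "_step_detector"), "step_detector")
  )
}

#' Detect steps in a recording
#'
#' Applies a [step_detector] to an [accel_recording] and returns the
#' ordered detected step times in seconds.
#'
#' @param detector A [step_detector].
#' @param recording An [accel_recording].
#' @return An object of class `step_detection`: a sorted numeric vector of
#'   step times (seconds), with the algorithm name attached.
#' @export
detect_steps <- function(detector, recording) {
  UseMethod("detect_steps")
}

#' @export
detect_steps.step_detector <- function(detector, recording) {
  if (!inherits(recording, "accel_recording"))
    stop("recording must be an accel_recording", call. = FALSE)
  times <- switch(detector$algorithm,
    peak = detect_peak(recording, detector$params),
    threshold = detect_threshold(recording, detector$params),
    autocorr = detect_autocorr(recording, detector$params)
  )
  structure(sort(as.numeric(times)),
            algorithm = detector$algorithm, class = "step_detection")
}

#' @rdname detect_steps
#' @param object A [step_detector].
#' @param newdata An [accel_recording].
#' @param ... Unused.
#' @export
predict.step_detector <- function(object, newdata, ...) {
  detect_steps(object, newdata)
}

#' @export
coef.step_detector <- function(object, ...) {
  unlist(unclass(object$params))
}

#' @export
print.step_detector <- function(x, ...) {
  cat(sprintf("<step_detector> algorithm: %s%s\n", x$algorithm,
              if (!is.null(x$tuning)) " (tuned)" else ""))
  p <- coef(x)
  cat(paste0("  ", names(p), " = ", format(p, trim = TRUE), collapse = "\n"),
      "\n")
  invisible(x)
}

#' @export
print.step_detection <- function(x, ...) {
  cat(sprintf("<step_detection> %d steps (%s algorithm)", length(x),
              attr(x, "algorithm")))
  if (length(x))
    cat(sprintf(", %.2f to %.2f s", min(x), max(x)))
  cat("\n")
  invisible(x)
}
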