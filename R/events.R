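#' Ground-truth gait events
#'
#' A `gait_events` object is a time-ordered table of annotated gait events.
#' Each event is either a *step* (a foot movement with a weight shift,
#' occurring inside a repeating pattern) or a *shift* (a foot movement
#' outside a repeating pattern: the first or last step of a bout, a pivot,
#' or a shuffle). Detected steps use the same container with label `"step"`.
#'
#' @param time_s Numeric vector of event times in seconds.
#' @param label Character vector, each `"step"` or `"shift"`.
#' @return An object of class `gait_events`: a data frame with columns
#'   `time_s` and `label`, sorted by time.
#' @export
gait_events <- function(time_s = numeric(), label = character()) {
  if (length(time_s) != length(label))
    stop("time_s and label must have equal length", call. = FALSE)
  bad <- setdiff(unique(label), c("step", "shift"))
  if (length(bad))
    stop("unknown event label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  ord <- order(time_s)
  structure(
    data.frame(time_s = as.numeric(time_s)[ord], label = as.character(label)[ord]),
    class = c("gait_events", "data.frame")
  )
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d events (%d steps, %d shifts)\n",
              nrow(x), sum(x$label == "step"), sum(x$label == "shift")))
  invisible(x)
}

#' Restrict events to a ground-truth mode
#'
#' Step counting can treat shifts either as countable steps or as
#' non-steps. `"steps_only"` drops shift rows; `"steps_and_shifts"` keeps
#' every event as a ground-truth step.
#'
#' @param events A [gait_events] object.
#' @param mode `"steps_only"` or `"steps_and_shifts"`.
#' @return A [gait_events] object.
#' @export
filter_events <- function(events, mode = c("steps_only", "steps_and_shifts")) {
  mode <- match.arg(mode)
  if (mode == "steps_only") events <- events[events$label == "step", , drop = FALSE]
  gait_events(events$time_s, events$label)
}

#' Read event annotations from CSV
#'
#' Expects columns `time_s` and `label` (values `step` or `shift`). Events
#' are returned sorted by time, restricted to the requested ground-truth
#' mode. An empty file (header only) yields an empty event set.
#'
#' @inheritParams filter_events
#' @param path CSV file path.
#' @return A [gait_events] object.
#' @export
read_events <- function(path, mode = c("steps_only", "steps_and_shifts")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, colClasses = c("numeric", "character"))
  if (!all(c("time_s", "label") %in% names(df)))
    stop("events CSV must have columns time_s and label", call. = FALSE)
  filter_events(gait_events(df$time_s, df$label), mode)
}

#' Write event annotations to CSV
#'
#' @param events A [gait_events] object (or detected step times as a
#'   numeric vector, written with label `step`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (is.numeric(events) && is.null(dim(events)))
    events <- gait_events(events, rep("step", length(events)))
  out <- data.frame(time_s = sprintf("%.6f", events$time_s), label = events$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
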