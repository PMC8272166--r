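# Scoring detections against ground truth: running count accuracy, one-to-
# one temporal matching within a tolerance, precision/recall/F1, and
# per-group aggregation.

#' Running count accuracy
#'
#' The ratio of detected to ground-truth step counts,
#' `RCA = n_detected / n_truth`. The ideal value is 1; values above 1 mean
#' the detector overestimates the step count, below 1 that it
#' underestimates.
#'
#' @param n_detected,n_truth Non-negative counts; `n_truth` must be
#'   positive.
#' @return The exact quotient.
#' @export
rca <- function(n_detected, n_truth) {
  if (n_truth <= 0)
    stop("RCA is undefined for zero ground-truth steps", call. = FALSE)
  n_detected / n_truth
}

#' Match detected steps to ground truth
#'
#' Greedy chronological one-to-one matching: ground-truth events are walked
#' in time order and each is paired with the nearest unmatched detection
#' within `tolerance_s` (ties go to the earlier detection). A matched pair
#' is excluded from any further pairing. Unmatched ground-truth events are
#' false negatives; unmatched detections are false positives. The tolerance
#' is closed: `|dt| <= tolerance_s` matches.
#'
#' The greedy scheme never exceeds the maximum-cardinality matching, and
#' achieves it whenever inter-event spacing exceeds twice the tolerance.
#'
#' @param detected_times,truth_times Sorted numeric vectors of times,
#'   seconds.
#' @param tolerance_s Matching tolerance in seconds (default 0.5).
#' @return `list(tp, fp, fn, pairs)` where `pairs` is a data frame with
#'   columns `truth_time` and `detected_time`.
#' @export
match_events <- function(detected_times, truth_times, tolerance_s = 0.5) {
  detected_times <- sort(as.numeric(detected_times))
  truth_times <- sort(as.numeric(truth_times))
  used <- logical(length(detected_times))
  pt <- numeric(0)
  pd <- numeric(0)
  for (tt in truth_times) {
    cand <- which(!used & abs(detected_times - tt) <= tolerance_s)
    if (length(cand)) {
      d <- abs(detected_times[cand] - tt)
      j <- cand[order(d, cand)][1L]  # nearest; ties -> earlier detection
      used[j] <- TRUE
      pt <- c(pt, tt)
      pd <- c(pd, detected_times[j])
    }
  }
  tp <- length(pt)
  list(tp = tp, fp = sum(!used), fn = length(truth_times) - tp,
       pairs = data.frame(truth_time = pt, detected_time = pd))
}

#' Evaluate a detection against ground truth
#'
#' Computes RCA, TP/FP/FN via [match_events()], precision, recall and F1
#' for one (recording, detector, ground-truth-mode) combination. F1 is 0
#' when there are no true positives.
#'
#' @param detected Detected step times: a numeric vector or
#'   `step_detection`.
#' @param truth Ground truth: a [gait_events] object (restricted by
#'   `mode`), or a numeric vector of times.
#' @param mode Ground-truth mode, see [filter_events()].
#' @param tolerance_s Matching tolerance, seconds.
#' @param algorithm,regime,position Optional tags carried into the report.
#' @return An object of class `eval_report`: a one-row data frame with
#'   columns `algorithm`, `regime`, `position`, `gt_mode`, `n_detected`,
#'   `n_truth`, `rca`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_detection <- function(detected, truth,
                               mode = c("steps_only", "steps_and_shifts"),
                               tolerance_s = 0.5,
                               algorithm = NA_character_,
                               regime = NA_character_,
                               position = NA_character_) {
  mode <- match.arg(mode)
  if (inherits(truth, "gait_events"))
    truth <- filter_events(truth, mode)$time_s
  truth <- sort(as.numeric(truth))
  if (is.na(algorithm) && !is.null(attr(detected, "algorithm")))
    algorithm <- attr(detected, "algorithm")
  detected <- sort(as.numeric(detected))
  n_det <- length(detected)
  n_truth <- length(truth)
  m <- match_events(detected, truth, tolerance_s)
  precision <- if (n_det > 0) m$tp / (m$tp + m$fp) else 0
  recall <- if (n_truth > 0) m$tp / (m$tp + m$fn) else 0
  f1 <- if (m$tp == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(data.frame(
    algorithm = algorithm, regime = regime, position = position,
    gt_mode = mode,
    n_detected = n_det, n_truth = n_truth,
    rca = rca(n_det, n_truth),
    tp = m$tp, fp = m$fp, fn = m$fn,
    precision = precision, recall = recall, f1 = f1
  ), class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s | %s gait | %s | %s\n  RCA %.3f (%d detected / %d truth); TP %d FP %d FN %d; P %.3f R %.3f F1 %.3f\n",
    x$algorithm, x$regime, x$position, x$gt_mode,
    x$rca, x$n_detected, x$n_truth, x$tp, x$fp, x$fn,
    x$precision, x$recall, x$f1
  ))
  invisible(x)
}

#' Aggregate evaluation reports
#'
#' Averages RCA and F1 within groups, reporting the mean and the sample
#' (n - 1) standard deviation across recordings; a single-recording group
#' reports a standard deviation of 0. Empty groups are omitted.
#'
#' @param reports A list of [evaluate_detection()] reports, or a data frame
#'   of stacked reports.
#' @param by Character vector of grouping columns (default
#'   `c("algorithm", "regime")`).
#' @return A data frame with one row per group: the grouping columns plus
#'   `n`, `mean_rca`, `sd_rca`, `mean_f1`, `sd_f1`.
#' @export
summarize_reports <- function(reports, by = c("algorithm", "regime")) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  if (is.null(reports) || !nrow(reports))
    stop("no reports to summarize", call. = FALSE)
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  key <- interaction(reports[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(reports, key), function(g) {
    cbind(g[1L, by, drop = FALSE],
          data.frame(n = nrow(g),
                     mean_rca = mean(g$rca), sd_rca = sd0(g$rca),
                     mean_f1 = mean(g$f1), sd_f1 = sd0(g$f1)))
  }))
  rownames(out) <- NULL
  out
}
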