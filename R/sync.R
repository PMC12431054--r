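#' Segment a recording session using the trigger channel
#'
#' One task window per maximal low-level (0 V) run of the trigger, ordered
#' in time. The first three windows are labelled `practice`,
#' `single_task`, `dual_task`; any further runs are labelled `extra_k`.
#' Runs shorter than `min_duration` are discarded as glitches.
#'
#' @param sync a `sync_signal` (levels 0/5 only).
#' @param min_duration shortest admissible task window, seconds.
#' @return data frame with columns `label`, `start`, `end` (half-open
#'   `[start, end)` windows, edge = time of the first sample at the new
#'   level).
#' @export
detect_task_windows <- function(sync, min_duration = 2) {
  stopifnot(inherits(sync, "sync_signal"))
  if (!all(sync$level %in% c(0, 5))) stop("trigger contains levels other than 0/5")
  low <- sync$level == 0
  if (!any(low)) return(data.frame(label = character(0), start = numeric(0),
                                   end = numeric(0)))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = (starts[r$values] - 1L) / sync$fs,
                     end = ends[r$values] / sync$fs)
  runs <- runs[runs$end - runs$start >= min_duration, , drop = FALSE]
  lab <- c("practice", "single_task", "dual_task")
  n <- nrow(runs)
  runs$label <- if (n) c(lab[seq_len(min(n, 3))],
                         if (n > 3) paste0("extra_", seq_len(n - 3))) else character(0)
  rownames(runs) <- NULL
  runs[, c("label", "start", "end")]
}

#' Slice a recording to a task window
#'
#' Keeps samples/frames with `start <= t < end`; metadata is preserved.
#'
#' @param recording an [imu_recording()] or `skeleton_recording`.
#' @param window a list/row with `start` and `end` (seconds).
#' @return an object of the same class as `recording`.
#' @export
slice_recording <- function(recording, window) {
  s <- window$start; e <- window$end
  if (inherits(recording, "imu_recording")) {
    keep <- recording$t >= s & recording$t < e
    if (!any(keep)) stop("window does not overlap the recording")
    imu_recording(recording$fs, recording$t[keep],
                  recording$gyro[keep, , drop = FALSE],
                  recording$accel[keep, , drop = FALSE],
                  recording$placement, recording$axis_convention)
  } else if (inherits(recording, "skeleton_recording")) {
    keep <- recording$time >= s & recording$time < e
    if (!any(keep)) stop("window does not overlap the recording")
    out <- recording[keep, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = class(recording), fps = attr(recording, "fps"),
              participant_id = attr(recording, "participant_id"))
  } else stop("unsupported recording type")
}

#' Detected gait events for one foot and modality
#'
#' @param foot `"left"` or `"right"`.
#' @param hs_times,to_times strictly increasing event times, seconds.
#' @param modality one of `"foot_imu"`, `"lumbar_imu"`, `"kinect"`,
#'   `"reference"`.
#' @param empty_warning flag set when detection found no peaks.
#' @return an object of class `event_series`.
#' @export
event_series <- function(foot, hs_times, to_times,
                         modality = c("foot_imu", "lumbar_imu", "kinect",
                                      "reference"),
                         empty_warning = FALSE) {
  modality <- match.arg(modality)
  if (is.unsorted(hs_times, strictly = TRUE) && length(hs_times) > 1)
    stop("hs_times must be strictly increasing")
  if (is.unsorted(to_times, strictly = TRUE) && length(to_times) > 1)
    stop("to_times must be strictly increasing")
  structure(list(foot = foot, hs = as.numeric(hs_times),
                 to = as.numeric(to_times), modality = modality,
                 empty_warning = empty_warning),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("Event series [%s, %s foot]: %d HS, %d TO%s\n", x$modality,
              x$foot, length(x$hs), length(x$to),
              if (isTRUE(x$empty_warning)) " (empty-detection warning)" else ""))
  invisible(x)
}

# Extract per-foot reference event series from a ground-truth train.
#' Reference event series from ground truth
#' @param events a `gait_events` train.
#' @param foot `"left"` or `"right"`.
#' @return an [event_series()] with modality `"reference"`.
#' @export
reference_events <- function(events, foot) {
  d <- events[events$foot == foot, ]
  event_series(foot, d$time[d$kind == "HS"], d$time[d$kind == "TO"],
               modality = "reference")
}

# Enforce strict HS/TO alternation on a merged candidate set: where two
# same-kind events occur without the other kind between them, keep the more
# extreme one (by the supplied strength value).
repair_alternation <- function(times, kinds, strength) {
  o <- order(times)
  times <- times[o]; kinds <- kinds[o]; strength <- strength[o]
  keep <- rep(TRUE, length(times))
  last <- 0L
  for (j in seq_along(times)) {
    if (last == 0L) { last <- j; next }
    if (kinds[j] == kinds[last]) {
      if (strength[j] > strength[last]) { keep[last] <- FALSE; last <- j }
      else keep[j] <- FALSE
    } else last <- j
  }
  list(times = times[keep], kinds = kinds[keep])
}
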