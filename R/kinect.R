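#' Select the participant among tracked bodies
#'
#' Among all body ids, scores each by frame coverage multiplied by the
#' fraction of frames whose pelvis (or first joint) lies inside the lateral
#' walkway gate, and returns the winner; ties are broken by the larger
#' total depth range travelled, since the participant walks the path while
#' bystanders stand beside it.
#'
#' @param rec a `skeleton_recording`.
#' @param walkway_gate numeric `(x_min, x_max)` in meters.
#' @param min_gate_fraction smallest admissible fraction of recording
#'   frames with the winning body inside the gate.
#' @return list of class `participant_track`: `body_id`, `frames` (the
#'   body's rows), `coverage`.
#' @export
select_participant <- function(rec, walkway_gate = c(-0.6, 0.6),
                               min_gate_fraction = 0.1) {
  if (!nrow(rec)) stop("empty skeleton recording")
  times <- sort(unique(rec$time))
  ids <- unique(rec$body_id)
  score <- vapply(ids, function(id) {
    d <- rec[rec$body_id == id, ]
    cov <- length(unique(d$time)) / length(times)
    ing <- mean(d$x >= walkway_gate[1] & d$x <= walkway_gate[2])
    cov * ing
  }, numeric(1))
  zrange <- vapply(ids, function(id) {
    d <- rec[rec$body_id == id, ]
    diff(range(d$z))
  }, numeric(1))
  ord <- order(-score, -zrange)
  best <- ids[ord[1]]
  d <- rec[rec$body_id == best, ]
  gate_frames <- unique(d$time[d$x >= walkway_gate[1] & d$x <= walkway_gate[2]])
  if (length(gate_frames) < min_gate_fraction * length(times))
    stop("no participant found inside the walkway gate")
  structure(list(body_id = best, frames = d,
                 coverage = length(unique(d$time)) / length(times)),
            class = "participant_track")
}

#' Resample a joint coordinate to a uniform grid
#'
#' Linear interpolation onto a uniform `fps` grid spanning the track;
#' depth-camera streams are specified only as "up to" their nominal rate,
#' and the Butterworth stage requires uniform sampling.
#'
#' @param track a `participant_track` (or its `frames`).
#' @param joint joint name.
#' @param fps target frame rate, Hz.
#' @return list with `t`, `x`, `y`, `z` on the uniform grid.
#' @export
resample_joint <- function(track, joint, fps = 30) {
  d <- if (inherits(track, "participant_track")) track$frames else track
  d <- d[d$joint == joint, ]
  d <- d[order(d$time), ]
  if (nrow(d) < 2) stop("not enough frames for joint ", joint)
  t <- seq(min(d$time), max(d$time), by = 1 / fps)
  list(t = t,
       x = stats::approx(d$time, d$x, t, rule = 2)$y,
       y = stats::approx(d$time, d$y, t, rule = 2)$y,
       z = stats::approx(d$time, d$z, t, rule = 2)$y)
}

#' Low-pass filter a joint movement signal
#'
#' Sixth-order Butterworth, 3 Hz cutoff, applied zero-phase.
#'
#' @param x uniformly sampled joint coordinate.
#' @param fps frame rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz.
#' @return filtered signal, same length.
#' @export
filter_joint_signal <- function(x, fps, cutoff_hz = 3) {
  if (fps < 7) stop("frame rate too low for a 3 Hz cutoff")
  sos_filtfilt(butter_sos(6, cutoff_hz, fps, type = "low"), x)
}

#' Second gradient of a joint position signal
#'
#' Discrete second gradient (central differences, one-sided at the edges)
#' scaled to m/s^2.
#'
#' @param position filtered position samples, meters.
#' @param fps frame rate, Hz.
#' @return acceleration samples, m/s^2.
#' @export
ankle_acceleration <- function(position, fps) {
  if (length(position) < 5) stop("signal too short for a second gradient")
  g1 <- num_gradient(position)
  num_gradient(g1) * fps^2
}

# numpy-style gradient: central differences inside, one-sided at the edges
num_gradient <- function(x) {
  n <- length(x)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
}

#' Detect gait events from ankle depth accelerations
#'
#' The ankle depth (z) acceleration is sign-corrected so that the
#' deceleration spike at ground contact appears as a positive peak
#' regardless of walking direction: the signal is multiplied by
#' `-direction_sign`, where `direction_sign` is the sign of the mean body
#' velocity along z over the pass. Local maxima of the corrected signal
#' are heel strikes and local minima toe-offs; per-foot alternation is
#' enforced as in the foot-IMU pipeline.
#'
#' @param accel_L,accel_R ankle depth accelerations from
#'   [ankle_acceleration()].
#' @param fps frame rate, Hz.
#' @param direction_sign +1 or -1, sign of the mean z-velocity.
#' @param params a [peak_params()].
#' @param t0 time of the first frame, seconds.
#' @return list with [event_series()] elements `left` and `right`,
#'   modality `"kinect"`.
#' @export
detect_kinect_events <- function(accel_L, accel_R, fps, direction_sign = -1,
                                 params = peak_params(), t0 = 0) {
  one <- function(acc, foot) {
    s <- -direction_sign * acc
    rp <- resolve_peak_params(params, s, fps)
    hs_idx <- find_signal_peaks(s, rp$min_height, rp$min_prominence,
                                rp$min_distance_samples)
    to_idx <- find_signal_peaks(-s, rp$min_height, rp$min_prominence,
                                rp$min_distance_samples)
    hs_idx <- consistent_peaks(s, hs_idx)
    to_idx <- consistent_peaks(s, to_idx)
    if (!length(hs_idx) && !length(to_idx))
      return(event_series(foot, numeric(0), numeric(0), "kinect",
                          empty_warning = TRUE))
    fix <- repair_alternation(c(hs_idx, to_idx),
                              c(rep("HS", length(hs_idx)),
                                rep("TO", length(to_idx))),
                              abs(s[c(hs_idx, to_idx)]))
    event_series(foot, t0 + (fix$times[fix$kinds == "HS"] - 1) / fps,
                 t0 + (fix$times[fix$kinds == "TO"] - 1) / fps, "kinect")
  }
  list(left = one(accel_L, "left"), right = one(accel_R, "right"))
}

#' Step and stride lengths from ankle depth at heel strikes
#'
#' Step length is the absolute depth difference between one ankle at its
#' heel strike and the other ankle at its preceding heel strike; stride
#' length is the absolute depth difference of the same ankle at
#' consecutive heel strikes. Positions are read from the frame nearest
#' each event time.
#'
#' @param zL,zR filtered ankle depth signals on the uniform grid.
#' @param t frame times for `zL`/`zR`, seconds.
#' @param events_L,events_R kinect [event_series()] per foot.
#' @return list with data frames `steps` (`time`, `foot`, `length`) and
#'   `strides` (`time`, `foot`, `length`), lengths in meters.
#' @export
kinect_lengths <- function(zL, zR, t, events_L, events_R) {
  z_at <- function(z, when) {
    ok <- when >= min(t) - 1e-9 & when <= max(t) + 1e-9
    out <- rep(NA_real_, length(when))
    if (any(!ok)) warning("event outside track span skipped")
    out[ok] <- z[vapply(when[ok], function(w) which.min(abs(t - w)), integer(1))]
    out
  }
  hs <- rbind(data.frame(time = events_L$hs,
                         foot = rep("left", length(events_L$hs))),
              data.frame(time = events_R$hs,
                         foot = rep("right", length(events_R$hs))))
  hs <- hs[order(hs$time), ]
  hs$z <- ifelse(hs$foot == "left", z_at(zL, hs$time), z_at(zR, hs$time))
  steps <- if (nrow(hs) > 1) {
    opp <- hs$foot[-1] != hs$foot[-nrow(hs)]  # a step joins opposite feet
    data.frame(time = hs$time[-1][opp], foot = hs$foot[-1][opp],
               length = abs(diff(hs$z))[opp])
  } else data.frame(time = numeric(0), foot = character(0), length = numeric(0))
  strides <- do.call(rbind, lapply(c("left", "right"), function(f) {
    d <- hs[hs$foot == f, ]
    if (nrow(d) < 2) return(NULL)
    data.frame(time = d$time[-1], foot = f, length = abs(diff(d$z)))
  }))
  if (is.null(strides))
    strides <- data.frame(time = numeric(0), foot = character(0),
                          length = numeric(0))
  list(steps = steps[!is.na(steps$length), , drop = FALSE],
       strides = strides[!is.na(strides$length), , drop = FALSE])
}
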