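#' Wavelet-differentiation configuration for the lumbar pipeline
#'
#' The first derivative of a Gaussian serves as the differentiating
#' wavelet. `scale` is expressed in samples and sets the kernel width (the
#' Gaussian sigma is `scale/8` samples, so the kernel spans about half a
#' step at the rule-derived scale). With `scale_rule =
#' "from_step_frequency"` the scale is derived at run time as
#' `fs / (2 * f_step)` with the step frequency taken from the dominant
#' spectral peak between 1.4 and 2.6 Hz.
#'
#' @param scale wavelet scale, samples (> 0); ignored when the rule is
#'   `"from_step_frequency"`.
#' @param scale_rule `"fixed"` or `"from_step_frequency"`.
#' @param sign +1 or -1; flips the output so that heel strikes appear as
#'   minima under the sensor's axis convention.
#' @return an object of class `cwt_config`.
#' @export
cwt_config <- function(scale = 35, scale_rule = c("fixed", "from_step_frequency"),
                       sign = 1) {
  scale_rule <- match.arg(scale_rule)
  if (scale <= 0) stop("scale must be positive")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  structure(list(scale = scale, scale_rule = scale_rule, sign = sign),
            class = "cwt_config")
}

#' Preprocess the lumbar anterior-posterior acceleration
#'
#' Linear detrending followed by a zero-phase second-order Butterworth
#' low-pass at 10 Hz.
#'
#' @param x anterior-posterior acceleration samples.
#' @param fs sampling rate, Hz.
#' @param lowpass_hz low-pass cutoff, Hz.
#' @return filtered samples, same length as `x`.
#' @export
preprocess_lumbar <- function(x, fs, lowpass_hz = 10) {
  if (length(x) < 2 * fs) stop("input shorter than 2 s")
  y <- detrend_linear(x)
  sos_filtfilt(butter_sos(2, lowpass_hz, fs, type = "low"), y)
}

# Step frequency (Hz) from the dominant spectral peak in [1.4, 2.6] Hz.
estimate_step_frequency <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  band <- which(f >= 1.4 & f <= 2.6)
  if (!length(band)) return(1.85)
  f[band[which.max(sp[band])]]
}

#' Integrate, then differentiate with a Gaussian-derivative wavelet
#'
#' The preprocessed signal is integrated by the cumulative trapezoid rule
#' and the integral is differentiated by correlation with a first
#' derivative of a Gaussian at the configured scale; the combination acts
#' as a smoothed band-pass identity around the step frequency, preserving
#' event extrema while suppressing integration drift.
#'
#' @param x preprocessed samples.
#' @param fs sampling rate, Hz.
#' @param cfg a [cwt_config()].
#' @return wavelet coefficient series, same length as `x`.
#' @export
integrate_then_cwt_differentiate <- function(x, fs, cfg = cwt_config()) {
  scale <- if (cfg$scale_rule == "from_step_frequency")
    fs / (2 * estimate_step_frequency(x, fs)) else cfg$scale
  if (scale >= length(x) / 4) stop("wavelet scale too large for the signal")
  t <- seq_along(x) / fs
  xi <- cumtrapz1(t, x)
  cwt_gaus1(xi, scale) * cfg$sign
}

# Correlate with the first derivative of a Gaussian whose sigma is scale/8
# samples (support +/- 4 sigma). Orientation is chosen so the output of
# differentiate(integrate(x)) correlates positively with x.
cwt_gaus1 <- function(x, scale) {
  s <- scale / 8
  half <- max(2L, ceiling(4 * s))
  k <- seq(-half, half)
  psi <- (k / s) * exp(-(k / s)^2 / 2) / (s * sqrt(2 * pi))
  y <- reflect_pad(x, half)
  out <- stats::filter(y, rev(psi), sides = 2)
  as.numeric(out[seq(half + 1L, half + length(x))])
}

#' Detect gait events from the wavelet-differentiated lumbar signal
#'
#' Local minima are heel strikes and local maxima toe-offs. A single
#' lumbar sensor cannot observe laterality directly, so heel strikes are
#' assigned alternately to the two feet starting from `first_side`, and
#' each toe-off takes the side opposite to the preceding heel strike.
#'
#' @param diff_signal output of [integrate_then_cwt_differentiate()].
#' @param fs sampling rate, Hz.
#' @param params a [peak_params()].
#' @param first_side side assigned to the first detected heel strike of
#'   each walking bout (side alternation restarts after an event-free gap
#'   longer than `bout_gap`, since the turn breaks strict alternation).
#' @param bout_gap gap, seconds, that starts a new walking bout.
#' @param t0 time of the first sample, seconds.
#' @return list with elements `left` and `right`, both [event_series()]
#'   with modality `"lumbar_imu"`.
#' @export
detect_lumbar_events <- function(diff_signal, fs, params = peak_params(),
                                 first_side = c("left", "right"),
                                 bout_gap = 1.2, t0 = 0) {
  first_side <- match.arg(first_side)
  rp <- resolve_peak_params(params, diff_signal, fs)
  # same-kind events recur once per STEP here (both feet in one stream)
  dist <- rp$min_distance_samples / 2
  hs_idx <- find_signal_peaks(-diff_signal, rp$min_height, rp$min_prominence, dist)
  to_idx <- find_signal_peaks(diff_signal, rp$min_height, rp$min_prominence, dist)
  if (!length(hs_idx)) {
    empty <- event_series("left", numeric(0), numeric(0), "lumbar_imu",
                          empty_warning = TRUE)
    empty_r <- event_series("right", numeric(0), numeric(0), "lumbar_imu",
                            empty_warning = TRUE)
    return(list(left = empty, right = empty_r))
  }
  fix <- repair_alternation(c(hs_idx, to_idx),
                            c(rep("HS", length(hs_idx)), rep("TO", length(to_idx))),
                            abs(diff_signal[c(hs_idx, to_idx)]))
  times <- t0 + (fix$times - 1) / fs
  kinds <- fix$kinds
  sides <- character(length(times))
  hs_pos <- which(kinds == "HS")
  alt <- c("left", "right")
  if (first_side == "right") alt <- rev(alt)
  bout <- cumsum(c(0, diff(times) > bout_gap))
  k <- 0L
  for (m in seq_along(hs_pos)) {
    i <- hs_pos[m]
    if (m > 1 && bout[i] != bout[hs_pos[m - 1L]]) k <- 0L  # restart per bout
    sides[i] <- alt[k %% 2L + 1L]
    k <- k + 1L
  }
  last_hs_side <- NA_character_
  cur_bout <- if (length(times)) bout[1] else 0
  for (i in seq_along(times)) {
    if (bout[i] != cur_bout) { cur_bout <- bout[i]; last_hs_side <- NA }
    if (kinds[i] == "HS") last_hs_side <- sides[i]
    else sides[i] <- if (is.na(last_hs_side)) {
      # a toe-off opening a bout lifts the foot that strikes first
      nxt <- hs_pos[hs_pos > i & bout[hs_pos] == bout[i]]
      if (length(nxt)) sides[nxt[1]] else alt[1]
    } else setdiff(c("left", "right"), last_hs_side)
  }
  mk <- function(side) event_series(
    side, times[kinds == "HS" & sides == side],
    times[kinds == "TO" & sides == side], "lumbar_imu")
  list(left = mk("left"), right = mk("right"))
}

#' Vertical excursion of the centre of mass over one step
#'
#' Double cumulative-trapezoid integration of the vertical acceleration
#' over `[t0, t1]`, with a drift reset after each integration stage: the
#' straight line through the first and last samples is removed, which
#' encodes the assumption that the centre of mass returns to the same
#' height (and the trunk to the same vertical velocity) at successive
#' heel strikes. Returns the peak-to-peak excursion of the resulting
#' position trace. Unlike a least-squares detrend, the endpoint line
#' leaves a one-period sinusoidal excursion untouched.
#'
#' @param vert_signal vertical acceleration samples for the whole recording.
#' @param fs sampling rate, Hz.
#' @param step_bounds numeric length-2 vector `(t0, t1)`, seconds, relative
#'   to the first sample.
#' @param t_start time of the first sample, seconds.
#' @return `h`, meters (>= 0).
#' @export
step_vertical_displacement <- function(vert_signal, fs, step_bounds,
                                       t_start = 0) {
  t <- t_start + (seq_along(vert_signal) - 1) / fs
  j <- which(t >= step_bounds[1] & t <= step_bounds[2])
  if (length(j) < 3) stop("step shorter than 3 samples")
  a <- vert_signal[j]
  endpoint_reset <- function(x) {
    n <- length(x)
    x - x[1] - (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  }
  v <- endpoint_reset(cumtrapz1(t[j], a))
  p <- endpoint_reset(cumtrapz1(t[j], v))
  max(p) - min(p)
}
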