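#' Peak-picking parameters for event detection
#'
#' @param min_height minimum peak height, signal units (applied to the
#'   signal after negation for minima).
#' @param min_prominence minimum topographic prominence; `NA` means the
#'   scale-free default, half the robust SD (1.4826 x MAD) of the signal.
#' @param min_distance minimum spacing between same-kind events, seconds;
#'   `NA` means half the stride time estimated from the autocorrelation.
#' @return an object of class `peak_params`.
#' @export
peak_params <- function(min_height = 0, min_prominence = NA,
                        min_distance = NA) {
  if (!is.na(min_height) && min_height < 0) stop("min_height must be >= 0")
  if (!is.na(min_prominence) && min_prominence < 0) stop("min_prominence must be >= 0")
  if (!is.na(min_distance) && min_distance < 0) stop("min_distance must be >= 0")
  structure(list(min_height = min_height, min_prominence = min_prominence,
                 min_distance = min_distance), class = "peak_params")
}

resolve_peak_params <- function(params, x, fs) {
  prom <- params$min_prominence
  # scale-free default with an amplitude floor: the robust SD of a sparse
  # lobe train underestimates the working scale when the baseline is
  # quiet, and the floor (15% of the working amplitude) rejects the
  # ringing side-lobes that steep zero-phase filtering leaves beside
  # isolated event lobes
  if (is.na(prom)) prom <- max(0.5 * stats::mad(x), 0.15 * max(abs(x)))
  dist <- params$min_distance
  if (is.na(dist)) dist <- 0.5 * estimate_stride_samples(x, fs) / fs
  list(min_height = params$min_height, min_prominence = prom,
       min_distance_samples = dist * fs)
}

#' Preprocess a foot-mounted medial-lateral gyroscope signal
#'
#' Two-stage zero-phase filtering: a 12th-order high-pass Butterworth in
#' second-order sections removes baseline drift, then a 216-coefficient
#' Hamming-window FIR low-pass removes high-frequency noise; the result is
#' mean-centred. Zero-phase (forward-backward) application keeps event
#' times unbiased.
#'
#' @param x medial-lateral angular velocity samples.
#' @param fs sampling rate, Hz.
#' @param highpass_hz high-pass cutoff, Hz.
#' @param lowpass_hz FIR low-pass cutoff, Hz.
#' @param fir_taps number of FIR coefficients.
#' @return filtered samples, same length as `x`, zero mean.
#' @export
preprocess_foot_gyro <- function(x, fs, highpass_hz = 0.5, lowpass_hz = 10,
                                 fir_taps = 216) {
  if (length(x) < 3 * fs) stop("input shorter than the 3 s filter warm-up")
  sos <- butter_sos(12, highpass_hz, fs, type = "high")
  y <- sos_filtfilt(sos, x)
  b <- signal::fir1(fir_taps - 1L, lowpass_hz / (fs / 2))
  y <- fir_filtfilt(b, y)
  y - mean(y)
}

#' Detect heel strikes and toe-offs from a filtered foot gyroscope signal
#'
#' Heel strikes are the negative peaks (minima) and toe-offs the positive
#' peaks (maxima) of the mean-centred medial-lateral angular velocity.
#' Peak constraints follow `params`; per-foot HS/TO alternation is enforced
#' by keeping the more extreme of two same-kind events detected without
#' the other kind between them.
#'
#' @param filtered output of [preprocess_foot_gyro()].
#' @param fs sampling rate, Hz.
#' @param foot which foot the sensor was mounted on.
#' @param params a [peak_params()].
#' @param t0 time of the first sample, seconds (event times are
#'   `t0 + (index - 1)/fs`).
#' @return an [event_series()] with modality `"foot_imu"`.
#' @export
detect_foot_events <- function(filtered, fs, foot = "left",
                               params = peak_params(), t0 = 0) {
  rp <- resolve_peak_params(params, filtered, fs)
  hs_idx <- find_signal_peaks(-filtered, rp$min_height, rp$min_prominence,
                              rp$min_distance_samples)
  to_idx <- find_signal_peaks(filtered, rp$min_height, rp$min_prominence,
                              rp$min_distance_samples)
  hs_idx <- consistent_peaks(filtered, hs_idx)
  to_idx <- consistent_peaks(filtered, to_idx)
  if (!length(hs_idx) && !length(to_idx)) {
    return(event_series(foot, numeric(0), numeric(0), "foot_imu",
                        empty_warning = TRUE))
  }
  fix <- repair_alternation(c(hs_idx, to_idx),
                            c(rep("HS", length(hs_idx)), rep("TO", length(to_idx))),
                            abs(filtered[c(hs_idx, to_idx)]))
  event_series(foot, t0 + (fix$times[fix$kinds == "HS"] - 1) / fs,
               t0 + (fix$times[fix$kinds == "TO"] - 1) / fs, "foot_imu")
}
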