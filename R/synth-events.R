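#' Gait profile describing the walking conditions to simulate
#'
#' Defaults reproduce typical single-task walking of older adults on a
#' 7 m out-and-back course: stride time 1.08 s, stance fraction 0.657 of
#' the stride, step length 0.655 m. The double-support fraction defaults to
#' `2 * stance_fraction - 1`, the only value consistent with both feet
#' sharing the same stance fraction in steady state.
#'
#' @param stride_time_mean,stride_time_sd stride duration, seconds.
#' @param stance_fraction fraction of the stride spent in stance, in (0,1).
#' @param double_support_fraction total double-support fraction of the
#'   stride; half of it is spent in initial double support.
#' @param step_length_mean,step_length_sd step length, meters.
#' @param path_length usable straight walking distance per pass, meters.
#' @param n_passes number of straight passes (2 = out and back).
#' @param asymmetry_ratio left/right step-length ratio.
#' @param turn_duration event-free turning interval between passes, seconds.
#' @param start_time time of the first stride onset, seconds.
#' @return an object of class `gait_profile`.
#' @export
gait_profile <- function(stride_time_mean = 1.08, stride_time_sd = 0.02,
                         stance_fraction = 0.657,
                         double_support_fraction = 2 * stance_fraction - 1,
                         step_length_mean = 0.655, step_length_sd = 0.02,
                         path_length = 7, n_passes = 2,
                         asymmetry_ratio = 1, turn_duration = 3,
                         start_time = 1) {
  p <- list(stride_time_mean = stride_time_mean,
            stride_time_sd = stride_time_sd,
            stance_fraction = stance_fraction,
            double_support_fraction = double_support_fraction,
            step_length_mean = step_length_mean,
            step_length_sd = step_length_sd,
            path_length = path_length, n_passes = as.integer(n_passes),
            asymmetry_ratio = asymmetry_ratio,
            turn_duration = turn_duration, start_time = start_time)
  if (!(double_support_fraction > 0 && double_support_fraction < stance_fraction &&
        stance_fraction < 1))
    stop("need 0 < double_support_fraction < stance_fraction < 1")
  if (stride_time_mean <= 0 || step_length_mean <= 0)
    stop("stride_time_mean and step_length_mean must be positive")
  if (stride_time_sd < 0 || step_length_sd < 0 || path_length <= 0 ||
      p$n_passes < 1 || asymmetry_ratio <= 0)
    stop("invalid gait profile")
  structure(p, class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("Gait profile:\n",
      sprintf("  stride time %.3f +/- %.3f s, stance fraction %.3f, DS fraction %.3f\n",
              x$stride_time_mean, x$stride_time_sd, x$stance_fraction,
              x$double_support_fraction),
      sprintf("  step length %.3f +/- %.3f m, %d pass(es) of %.1f m\n",
              x$step_length_mean, x$step_length_sd, x$n_passes, x$path_length))
  invisible(x)
}

#' Sensor noise description
#'
#' @param gaussian_sd white-noise standard deviation, in signal units.
#' @param drift_amplitude amplitude of a slow sinusoidal baseline drift.
#' @param drift_period drift period, seconds.
#' @param seed RNG seed used when the noise is realised.
#' @return an object of class `sensor_noise`.
#' @export
sensor_noise <- function(gaussian_sd = 0, drift_amplitude = 0,
                         drift_period = 60, seed = 1) {
  if (gaussian_sd < 0 || drift_amplitude < 0 || drift_period <= 0)
    stop("invalid sensor noise specification")
  structure(list(gaussian_sd = gaussian_sd, drift_amplitude = drift_amplitude,
                 drift_period = drift_period, seed = as.integer(seed)),
            class = "sensor_noise")
}

#' Generate a ground-truth heel-strike / toe-off event train
#'
#' The left foot initiates each pass. Within a stride of duration `T`
#' starting at a left heel strike, the contralateral toe-off occurs at
#' `+ds/2 * T`, the contralateral heel strike at the half stride, and the
#' ipsilateral toe-off at `+stance_fraction * T`. Stride durations and step
#' lengths are drawn from normal distributions truncated at three standard
#' deviations; each pass ends before the cumulative distance would exceed
#' the path length, and passes are separated by an event-free turn.
#'
#' @param profile a [gait_profile()].
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return a `gait_events` data frame with columns `time`, `foot`, `kind`,
#'   `pass`, `step_length` (meters, `NA` where no preceding contralateral
#'   placement exists) and `position` (within-pass path coordinate of the
#'   placement, `NA` for toe-offs).
#' @export
generate_event_sequence <- function(profile, seed = 1) {
  stopifnot(inherits(profile, "gait_profile"))
  pr <- profile
  sL_mean <- pr$step_length_mean * 2 * pr$asymmetry_ratio / (1 + pr$asymmetry_ratio)
  sR_mean <- pr$step_length_mean * 2 / (1 + pr$asymmetry_ratio)
  if (sL_mean + sR_mean + 3 * 2 * pr$step_length_sd > pr$path_length)
    stop("a single stride can exceed path_length: unusable geometry")
  with_seed(seed, {
    rows <- list()
    t_cursor <- pr$start_time
    for (pass in seq_len(pr$n_passes)) {
      n_max <- ceiling(pr$path_length / (sL_mean + sR_mean)) + 3L
      Ts <- rnorm_trunc3(n_max, pr$stride_time_mean, pr$stride_time_sd)
      sR <- rnorm_trunc3(n_max, sR_mean, pr$step_length_sd)
      sL <- rnorm_trunc3(n_max, sL_mean, pr$step_length_sd)
      dist <- cumsum(sR + sL)
      n <- max(1L, sum(dist <= pr$path_length))
      u <- t_cursor + c(0, cumsum(Ts[seq_len(n)]))
      swing <- (1 - pr$stance_fraction) * Ts[1]
      ev <- list(data.frame(time = u[1] - swing, foot = "left", kind = "TO",
                            pass = pass, step_length = NA_real_,
                            position = NA_real_))
      posL <- 0
      for (i in seq_len(n)) {
        Ti <- Ts[i]
        posR <- posL + sR[i]
        ev[[length(ev) + 1L]] <- data.frame(
          time = c(u[i], u[i] + pr$double_support_fraction / 2 * Ti,
                   u[i] + Ti / 2, u[i] + pr$stance_fraction * Ti),
          foot = c("left", "right", "right", "left"),
          kind = c("HS", "TO", "HS", "TO"),
          pass = pass,
          step_length = c(if (i == 1) NA_real_ else sL[i - 1], NA, sR[i], NA),
          position = c(posL, NA, posR, NA))
        posL <- posR + sL[i]
      }
      ev[[length(ev) + 1L]] <- data.frame(
        time = u[n + 1], foot = "left", kind = "HS", pass = pass,
        step_length = sL[n], position = posL)
      rows[[pass]] <- do.call(rbind, ev)
      t_cursor <- u[n + 1] + pr$turn_duration + (1 - pr$stance_fraction) * pr$stride_time_mean
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$time), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("gait_events", "data.frame")
    attr(out, "profile") <- pr
    pw <- do.call(rbind, lapply(split(out, out$pass), function(d)
      data.frame(pass = d$pass[1], start = min(d$time), end = max(d$time))))
    rownames(pw) <- NULL
    attr(out, "pass_windows") <- pw
    out
  })
}

#' Check the structural invariants of a ground-truth event train
#'
#' Verifies strict temporal ordering within passes, strict per-foot
#' HS/TO alternation, and the steady-state cyclic order (each heel strike
#' is followed by the opposite foot's toe-off).
#'
#' @param events a `gait_events` data frame.
#' @return `TRUE` invisibly; errors describe the violated invariant.
#' @export
validate_gait_events <- function(events) {
  for (p in unique(events$pass)) {
    d <- events[events$pass == p, ]
    if (any(diff(d$time) <= 0)) stop("event times not strictly increasing in pass ", p)
    for (f in c("left", "right")) {
      k <- d$kind[d$foot == f]
      if (length(k) > 1 && any(k[-1] == k[-length(k)]))
        stop("HS/TO alternation violated for ", f, " foot in pass ", p)
    }
    hs <- d[d$kind == "HS", ]
    if (nrow(hs) > 1 && any(hs$foot[-1] == hs$foot[-nrow(hs)]))
      stop("consecutive heel strikes on the same foot in pass ", p)
    # each HS (except the last of the pass) is followed by the opposite TO
    for (i in which(d$kind == "HS")) {
      later <- d[d$time > d$time[i], ]
      if (nrow(later) && later$kind[1] == "TO" && later$foot[1] == d$foot[i])
        stop("ipsilateral toe-off directly follows a heel strike in pass ", p)
    }
  }
  invisible(TRUE)
}
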