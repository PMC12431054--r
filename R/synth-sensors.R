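#' Construct an inertial recording object
#'
#' @param fs sampling rate, Hz.
#' @param t time grid, seconds (uniform).
#' @param gyro n-by-3 matrix of angular velocity, rad/s (columns gx, gy, gz;
#'   gy is the medial-lateral axis for foot placements).
#' @param accel n-by-3 matrix of acceleration, m/s^2 (columns ax, ay, az;
#'   for the lumbar placement ax is vertical and az anterior-posterior).
#' @param placement `"left_foot"`, `"right_foot"` or `"lumbar"`.
#' @param axis_convention free-text axis metadata.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(fs, t, gyro, accel, placement,
                          axis_convention = "y outward from skin, z toward ground") {
  stopifnot(length(t) == nrow(gyro), nrow(gyro) == nrow(accel))
  if (length(t) > 1 && max(abs(diff(t) - 1 / fs)) >= 1e-9)
    stop("time grid is not uniform at 1/fs")
  structure(list(fs = fs, t = t, gyro = gyro, accel = accel,
                 placement = placement, axis_convention = axis_convention),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording [%s]: %d samples at %g Hz (%.1f s)\n",
              x$placement, length(x$t), x$fs, diff(range(x$t))))
  invisible(x)
}

gauss_lobes <- function(t, centers, amps, sigma) {
  out <- numeric(length(t))
  if (!length(centers)) return(out)
  dt <- t[2] - t[1]
  half <- ceiling(5 * sigma / dt)
  for (i in seq_along(centers)) {
    j0 <- max(1L, floor((centers[i] - t[1]) / dt) - half)
    j1 <- min(length(t), ceiling((centers[i] - t[1]) / dt) + half)
    j <- j0:j1
    out[j] <- out[j] + amps[i] * exp(-((t[j] - centers[i])^2) / (2 * sigma^2))
  }
  out
}

noise_channel <- function(t, noise, stream) {
  with_seed(sub_seed(noise$seed, stream), {
    n <- stats::rnorm(length(t), 0, noise$gaussian_sd)
  }) + noise$drift_amplitude * sin(2 * pi * t / noise$drift_period)
}

white_channel <- function(t, noise, stream) {
  with_seed(sub_seed(noise$seed, stream), stats::rnorm(length(t), 0, noise$gaussian_sd))
}

# previous heel-strike time (either foot) before each heel strike of `foot`
step_windows_for_foot <- function(events, foot) {
  hs <- events[events$kind == "HS", ]
  own <- which(hs$foot == foot & !is.na(hs$step_length))
  own <- own[own > 1]
  own <- own[hs$pass[own] == hs$pass[own - 1L]]
  data.frame(t0 = hs$time[own - 1L], t1 = hs$time[own],
             step_length = hs$step_length[own])
}

#' Synthesize a foot-mounted gyroscope/accelerometer stream
#'
#' The medial-lateral angular-velocity channel (gy) carries a Gaussian
#' negative lobe at each ground-truth heel strike of the chosen foot and a
#' positive lobe at each toe-off, over white noise and a slow sinusoidal
#' drift. The accelerometer z channel embeds, during each of the foot's
#' steps, a sinusoidal vertical-acceleration wave whose peak-to-peak range
#' equals `(step_length / weinberg_k)^4`, so that a Weinberg-type quartic
#' root recovers the step length once calibrated.
#'
#' @param events a `gait_events` train from [generate_event_sequence()].
#' @param foot `"left"` or `"right"`.
#' @param fs sampling rate, Hz (>= 64).
#' @param noise a [sensor_noise()] (units rad/s for the gyro channels).
#' @param lobe_width full width of the event lobes, seconds (about 4 sigma).
#' @param hs_amplitude,to_amplitude lobe magnitudes, rad/s.
#' @param weinberg_k constant tying the embedded acceleration range to the
#'   step length.
#' @param duration recording length, seconds; default covers all events
#'   plus one second.
#' @return an [imu_recording()].
#' @export
synthesize_foot_gyro <- function(events, foot = c("left", "right"), fs = 128,
                                 noise = sensor_noise(),
                                 lobe_width = 0.12, hs_amplitude = 5,
                                 to_amplitude = 3, weinberg_k = 0.5,
                                 duration = NULL) {
  foot <- match.arg(foot)
  if (fs < 64) stop("fs must be at least 64 Hz")
  if (is.null(duration)) duration <- max(events$time) + 1
  t <- (seq_len(round(duration * fs)) - 1) / fs
  sigma <- lobe_width / 4
  own <- events[events$foot == foot, ]
  gy <- gauss_lobes(t, own$time[own$kind == "HS"],
                    rep(-hs_amplitude, sum(own$kind == "HS")), sigma) +
        gauss_lobes(t, own$time[own$kind == "TO"],
                    rep(to_amplitude, sum(own$kind == "TO")), sigma) +
        noise_channel(t, noise, 1L)
  sw <- step_windows_for_foot(events, foot)
  az <- rep(9.81, length(t))
  for (i in seq_len(nrow(sw))) {
    r <- (sw$step_length[i] / weinberg_k)^4
    j <- which(t >= sw$t0[i] & t <= sw$t1[i])
    az[j] <- az[j] + r / 2 * sin(2 * pi * (t[j] - sw$t0[i]) / (sw$t1[i] - sw$t0[i]))
  }
  gyro <- cbind(gx = white_channel(t, noise, 2L), gy = gy,
                gz = white_channel(t, noise, 3L))
  accel <- cbind(ax = white_channel(t, noise, 4L),
                 ay = white_channel(t, noise, 5L),
                 az = az + white_channel(t, noise, 6L))
  imu_recording(fs, t, gyro, accel,
                placement = paste0(foot, "_foot"))
}

#' Synthesize a lumbar accelerometer stream
#'
#' The anterior-posterior channel (az) carries a negative Gaussian lobe at
#' every heel strike and a positive lobe at every toe-off of either foot.
#' The vertical channel (ax) carries gravity plus, over each step interval
#' (heel strike to the next contralateral heel strike), one period of a
#' sine acceleration wave whose double integral has peak-to-peak
#' excursion `h` obtained by inverting the inverted-pendulum relation
#' `step_length = 2*sqrt(2*l*h - h^2)` (smaller root), so the lumbar
#' pipeline can recover the embedded step length.
#'
#' @inheritParams synthesize_foot_gyro
#' @param pendulum_length pendulum length `l`, meters.
#' @param hs_amplitude,to_amplitude anterior-posterior lobe magnitudes, m/s^2.
#' @param event_jitter_sd Gaussian timing jitter applied to the
#'   anterior-posterior event lobes, seconds; models the indirect coupling
#'   of trunk accelerations to foot-contact events. Zero by default.
#' @param to_time_bias systematic shift of the toe-off lobes, seconds
#'   (negative = early); trunk deceleration precedes the actual toe-off,
#'   which is why lumbar-derived stance times underestimate walkway
#'   stance. Zero by default.
#' @param to_jitter_sd additional Gaussian timing jitter applied to the
#'   toe-off lobes only, seconds; toe-off is far less distinct in trunk
#'   accelerations than the heel-strike impact. Zero by default.
#' @return an [imu_recording()] with placement `"lumbar"`.
#' @export
synthesize_lumbar_accel <- function(events, fs = 128, noise = sensor_noise(),
                                    pendulum_length = 0.94,
                                    hs_amplitude = 1.5, to_amplitude = 1.0,
                                    lobe_width = 0.10, event_jitter_sd = 0,
                                    to_time_bias = 0, to_jitter_sd = 0,
                                    duration = NULL) {
  if (pendulum_length <= 0) stop("pendulum_length must be positive")
  sl <- events$step_length[!is.na(events$step_length)]
  if (any(sl >= 2 * pendulum_length))
    stop("step length >= 2 * pendulum_length: pendulum relation has no real solution")
  if (is.null(duration)) duration <- max(events$time) + 1
  t <- (seq_len(round(duration * fs)) - 1) / fs
  sigma <- lobe_width / 4
  is_to <- events$kind == "TO"
  centers <- events$time + ifelse(is_to, to_time_bias, 0)
  amps <- ifelse(events$kind == "HS", -hs_amplitude, to_amplitude)
  if (event_jitter_sd > 0 || to_jitter_sd > 0) {
    centers <- centers + with_seed(sub_seed(noise$seed, 17L), {
      stats::rnorm(length(centers), 0, event_jitter_sd) +
        ifelse(is_to, stats::rnorm(length(centers), 0, to_jitter_sd), 0)
    })
  }
  az <- gauss_lobes(t, centers, amps, sigma) + noise_channel(t, noise, 7L)
  ax <- rep(9.81, length(t))
  hs <- events[events$kind == "HS", ]
  for (i in seq_len(nrow(hs))[-1]) {
    if (hs$pass[i] != hs$pass[i - 1L] || is.na(hs$step_length[i])) next
    SL <- hs$step_length[i]
    h <- pendulum_length - sqrt(pendulum_length^2 - SL^2 / 4)
    t0 <- hs$time[i - 1L]; t1 <- hs$time[i]
    w <- 2 * pi / (t1 - t0)
    j <- which(t >= t0 & t <= t1)
    # one sine period per step: its double integral is exactly a sine of
    # peak-to-peak h, and it is invariant under the per-stage linear
    # drift reset applied downstream
    ax[j] <- ax[j] + h * w^2 / 2 * sin(w * (t[j] - t0))
  }
  gyro <- cbind(gx = white_channel(t, noise, 8L),
                gy = white_channel(t, noise, 9L),
                gz = white_channel(t, noise, 10L))
  accel <- cbind(ax = ax + white_channel(t, noise, 11L),
                 ay = white_channel(t, noise, 12L),
                 az = az)
  imu_recording(fs, t, gyro, accel, placement = "lumbar",
                axis_convention = "x vertical, z anterior-posterior")
}

# Smooth 0..1 advance profile built from Gaussian acceleration lobes at the
# boundaries (used for slow repositioning during the turn).
phi_ramp <- function(t, a, b, sigma) {
  psi <- function(u) u * stats::pnorm(u) + stats::dnorm(u)
  sigma * (psi((t - a) / sigma) - psi((t - b) / sigma)) / (b - a)
}

# Swing velocity profile on the frame grid: a Gaussian-smoothed onset whose
# acceleration peaks exactly at toe-off `a`, a plateau, and a raised-cosine
# stop ending exactly at heel strike `b` with the deceleration peak at
# b - stop_width/2. The foot is stationary at `b`, so depth read at a heel
# strike equals the placement.
swing_velocity <- function(t, a, b, onset_sigma = 0.05, stop_width = 0.04) {
  v <- stats::pnorm((t - a) / onset_sigma)
  dec <- t > b - stop_width & t <= b
  v[dec] <- v[dec] * (1 + cos(pi * (t[dec] - (b - stop_width)) / stop_width)) / 2
  v[t > b] <- 0
  v
}

#' Synthesize a depth-camera skeleton recording
#'
#' One persistent body id carries the participant for the whole recording:
#' ankle depth (z) is constant during that foot's stance and advances
#' smoothly during swing by the ground-truth step geometry, decreasing on
#' outbound passes and increasing on the return; ankle height (y) shows a
#' mid-swing bump. The swing velocity rises with a Gaussian-smoothed onset
#' whose acceleration peaks exactly at toe-off and stops with a 40 ms
#' raised-cosine whose deceleration peaks just before heel strike, so the
#' foot is stationary at contact and the depth read at a heel strike
#' equals the ground-truth placement. `clutter` additional bodies appear
#' and disappear with changing body ids, laterally offset from the
#' walkway.
#'
#' @inheritParams synthesize_foot_gyro
#' @param fps frame rate, Hz (<= 30).
#' @param clutter number of bystander bodies.
#' @param noise a [sensor_noise()]; `gaussian_sd` in meters of joint position.
#' @param swing_sigma Gaussian sigma of the swing-onset acceleration lobe,
#'   seconds.
#' @param z_start depth of the starting line from the camera, meters.
#' @return an object of class `skeleton_recording`: a long data frame with
#'   columns `time`, `body_id`, `joint`, `x`, `y`, `z`.
#' @export
synthesize_skeleton <- function(events, fps = 30, clutter = 0,
                                noise = sensor_noise(), swing_sigma = 0.05,
                                z_start = 7.6, duration = NULL) {
  if (fps > 30) stop("fps must be at most 30")
  if (clutter < 0) stop("clutter must be non-negative")
  if (is.null(duration)) duration <- max(events$time) + 1
  t <- (seq_len(round(duration * fps)) - 1) / fps
  profile <- attr(events, "profile")
  s0 <- if (!is.null(profile)) profile$step_length_mean else
    mean(events$step_length, na.rm = TRUE)

  # the continuous motion is built on a fine internal grid and sampled at
  # the frame times, as the camera does; integrating directly on the
  # coarse frame grid would misplace the sharp stop by up to a frame
  tt <- (seq_len(round(duration * fps * 8)) - 1) / (fps * 8)

  foot_depth <- function(foot) {
    z <- numeric(length(tt))
    z_cur <- NA_real_
    last_t <- 0
    segs <- list()
    for (p in sort(unique(events$pass))) {
      d <- events[events$pass == p & events$foot == foot, ]
      dirn <- if (p %% 2 == 1) -1 else 1
      # within-pass depth of a path position
      pass_all <- events[events$pass == p, ]
      base <- if (p %% 2 == 1) z_start else z_turn
      to_t <- d$time[d$kind == "TO"]
      hs <- d[d$kind == "HS", ]
      z_of <- function(pos) base + dirn * pos
      stand <- z_of(-s0)
      if (is.na(z_cur)) z_cur <- stand else {
        # slow smooth repositioning during the turn, well below gait
        # accelerations so it cannot masquerade as a step
        a <- last_t + 0.4
        b <- min(pass_all$time) - 0.3
        segs[[length(segs) + 1L]] <- list(a = a, b = b, from = z_cur,
                                          to = stand, sigma = (b - a) / 5)
        z_cur <- stand
      }
      n_sw <- min(length(to_t), nrow(hs))
      for (k in seq_len(n_sw)) {
        zt <- z_of(hs$position[k])
        segs[[length(segs) + 1L]] <- list(a = to_t[k], b = hs$time[k],
                                          from = z_cur, to = zt,
                                          kind = "swing")
        z_cur <- zt
      }
      last_t <- max(pass_all$time)
      if (p %% 2 == 1) z_turn <- z_start - max(pass_all$position, na.rm = TRUE)
    }
    z[] <- segs[[1]]$from
    for (s in segs) {
      frac <- if (identical(s$kind, "swing")) {
        v <- swing_velocity(tt, s$a, s$b, onset_sigma = swing_sigma)
        cv <- cumsum((v + c(0, v[-length(v)])) / 2)  # trapezoid areas
        if (cv[length(cv)] > 0) cv / max(cv) else cv
      } else phi_ramp(tt, s$a, s$b, s$sigma)
      z <- z + (s$to - s$from) * frac
    }
    stats::approx(tt, z, t, rule = 2)$y
  }

  zL <- foot_depth("left")
  zR <- foot_depth("right")

  swing_bump <- function(foot) {
    y <- rep(0.08, length(t))
    d <- events[events$foot == foot, ]
    to_t <- d$time[d$kind == "TO"]
    hs_t <- d$time[d$kind == "HS"]
    for (a in to_t) {
      b <- hs_t[hs_t > a]
      if (!length(b)) next
      mid <- (a + min(b)) / 2
      y <- y + 0.05 * exp(-((t - mid)^2) / (2 * 0.06^2))
    }
    y
  }

  jn <- function(v, stream) v + white_channel(t, noise, stream)
  part <- rbind(
    data.frame(time = t, body_id = 1L, joint = "left_ankle",
               x = jn(rep(-0.12, length(t)), 21L), y = jn(swing_bump("left"), 22L),
               z = jn(zL, 23L)),
    data.frame(time = t, body_id = 1L, joint = "right_ankle",
               x = jn(rep(0.12, length(t)), 24L), y = jn(swing_bump("right"), 25L),
               z = jn(zR, 26L)),
    data.frame(time = t, body_id = 1L, joint = "pelvis",
               x = jn(rep(0, length(t)), 27L), y = jn(rep(0.95, length(t)), 28L),
               z = jn((zL + zR) / 2, 29L)))

  bodies <- list(part)
  if (clutter > 0) {
    bodies <- c(bodies, with_seed(sub_seed(noise$seed, 99L), {
      lapply(seq_len(clutter), function(k) {
        t0 <- stats::runif(1, 0, 0.6 * duration)
        t1 <- t0 + stats::runif(1, 0.1, 0.35) * duration
        tk <- t[t >= t0 & t <= t1]
        if (length(tk) < 4) tk <- t[seq_len(4)]
        # changing ids: split the visit into chunks with fresh ids
        chunk <- cut(seq_along(tk), breaks = sample(2:3, 1), labels = FALSE)
        xk <- (0.9 + stats::runif(1, 0, 0.4)) * sample(c(-1, 1), 1)
        zk <- stats::runif(1, 2, 7) +
          cumsum(stats::rnorm(length(tk), 0, 0.01))
        do.call(rbind, lapply(unique(chunk), function(cc) {
          sel <- chunk == cc
          id <- 100L + 10L * k + cc
          do.call(rbind, lapply(c("left_ankle", "right_ankle", "pelvis"),
                                function(j) {
            data.frame(time = tk[sel], body_id = id, joint = j,
                       x = xk + stats::rnorm(sum(sel), 0, 0.01),
                       y = ifelse(j == "pelvis", 0.95, 0.08) +
                         stats::rnorm(sum(sel), 0, 0.01),
                       z = zk[sel] + stats::rnorm(sum(sel), 0, 0.005))
          }))
        }))
      })
    }))
  }
  out <- do.call(rbind, bodies)
  out <- out[order(out$time, out$body_id), ]
  rownames(out) <- NULL
  structure(out, class = c("skeleton_recording", "data.frame"),
            fps = fps, participant_id = 1L)
}

#' Synthesize a TTL synchronization trigger channel
#'
#' 5 V while idle, 0 V during active task windows, with sample-exact edges.
#'
#' @param task_windows data frame with columns `start`, `end` (seconds), or
#'   a list of length-2 vectors; windows must be disjoint.
#' @param fs sampling rate, Hz.
#' @param total_duration recording length, seconds.
#' @return an object of class `sync_signal`: list with `fs` and `level`.
#' @export
synthesize_trigger <- function(task_windows, fs, total_duration) {
  w <- as_windows(task_windows)
  if (nrow(w)) {
    w <- w[order(w$start), , drop = FALSE]
    if (any(w$end[-nrow(w)] > w$start[-1])) stop("task windows overlap")
    if (any(w$start < 0) || any(w$end > total_duration))
      stop("task windows outside [0, total_duration]")
  }
  n <- floor(total_duration * fs)
  level <- rep(5, n)
  for (i in seq_len(nrow(w))) {
    lo <- floor(w$start[i] * fs)          # 0-based sample index
    hi <- ceiling(w$end[i] * fs) - 1L
    if (hi >= lo) level[seq(lo + 1L, min(n, hi + 1L))] <- 0
  }
  structure(list(fs = fs, level = level), class = "sync_signal")
}

as_windows <- function(x) {
  if (is.data.frame(x)) return(x[, c("start", "end"), drop = FALSE])
  if (!length(x)) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = vapply(x, `[`, numeric(1), 1),
             end = vapply(x, `[`, numeric(1), 2))
}
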