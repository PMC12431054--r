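#' Default run configuration
#'
#' All tunables of the simulator and the three detection pipelines in one
#' JSON-serialisable list. Cohort-level means mirror typical single-task
#' (stride 1.08 s, step 0.655 m) and dual-task (stride 1.16 s, step
#' 0.62 m) walking of older adults; sensor noise defaults are stated in
#' each stream's physical units.
#'
#' @param n_subjects cohort size.
#' @return nested configuration list.
#' @export
default_config <- function(n_subjects = 18) {
  list(
    cohort = list(
      n_subjects = n_subjects,
      tasks = list(
        single_task = list(stride_time_mean = 1.08, stride_between_sd = 0.08,
                           step_length_mean = 0.655, step_between_sd = 0.06),
        dual_task = list(stride_time_mean = 1.16, stride_between_sd = 0.12,
                         step_length_mean = 0.62, step_between_sd = 0.08))),
    profile = list(stride_time_sd = 0.02, stance_fraction = 0.657,
                   step_length_sd = 0.02, path_length = 7, n_passes = 2,
                   turn_duration = 3),
    sensors = list(
      fs_imu = 128, fps = 30, clutter = 1,
      foot_noise = list(gaussian_sd = 0.25, drift_amplitude = 0.5,
                        drift_period = 60),
      lumbar_noise = list(gaussian_sd = 0.08, drift_amplitude = 0.2,
                          drift_period = 60),
      lumbar_event_jitter_sd = 0.01, lumbar_to_jitter_sd = 0.02,
      lumbar_to_bias = -0.10,
      kinect_noise = list(gaussian_sd = 0.005),
      weinberg_k = 0.5),
    analysis = list(
      foot_highpass_hz = 0.5, foot_lowpass_hz = 10, fir_taps = 216,
      lumbar_lowpass_hz = 10,
      cwt = list(scale_rule = "from_step_frequency", scale = 35, sign = 1),
      kinect_cutoff_hz = 3, gate = c(-0.6, 0.6),
      pendulum_length = 0.94,
      bout_gap = 1.2, max_stride_time = 2))
}

derive_seed <- function(seed, ...) {
  k <- c(...)
  as.integer((as.numeric(seed) * 100003 + sum(k * 257^(seq_along(k) - 1))) %%
               2147483629)
}

#' Draw one subject's gait profile from the cohort distribution
#'
#' Stride time and step length are drawn (truncated at three SD) with a
#' negative correlation of -0.5: slower walkers take shorter steps.
#'
#' @param config a [default_config()] list.
#' @param task `"single_task"` or `"dual_task"`.
#' @param seed RNG seed.
#' @return a [gait_profile()].
#' @export
subject_profile <- function(config, task = "single_task", seed = 1) {
  tk <- config$cohort$tasks[[task]]
  pr <- config$profile
  with_seed(seed, {
    u <- stats::rnorm(1); v <- stats::rnorm(1)
    u <- max(-3, min(3, u)); v <- max(-3, min(3, v))
    stride <- tk$stride_time_mean + tk$stride_between_sd * u
    step <- tk$step_length_mean + tk$step_between_sd * (-0.5 * u + sqrt(0.75) * v)
    gait_profile(stride_time_mean = max(0.7, stride),
                 stride_time_sd = pr$stride_time_sd,
                 stance_fraction = pr$stance_fraction,
                 step_length_mean = max(0.3, step),
                 step_length_sd = pr$step_length_sd,
                 path_length = pr$path_length, n_passes = pr$n_passes,
                 turn_duration = pr$turn_duration)
  })
}

#' Simulate one walking trial (all modalities)
#'
#' @param profile a [gait_profile()].
#' @param config a [default_config()] list.
#' @param seed RNG seed.
#' @param noiseless logical; zero all sensor noise and lumbar event jitter.
#' @return list with `truth`, `foot_left`, `foot_right`, `lumbar`,
#'   `skeleton`.
#' @export
simulate_trial <- function(profile, config = default_config(), seed = 1,
                           noiseless = FALSE) {
  sn <- config$sensors
  mk_noise <- function(spec, s) {
    if (noiseless) sensor_noise(0, 0, 60, seed = s)
    else sensor_noise(spec$gaussian_sd,
                      if (is.null(spec$drift_amplitude)) 0 else spec$drift_amplitude,
                      if (is.null(spec$drift_period)) 60 else spec$drift_period,
                      seed = s)
  }
  truth <- generate_event_sequence(profile, seed = derive_seed(seed, 1))
  jit <- if (noiseless) 0 else sn$lumbar_event_jitter_sd
  list(
    truth = truth,
    foot_left = synthesize_foot_gyro(
      truth, "left", sn$fs_imu, mk_noise(sn$foot_noise, derive_seed(seed, 2)),
      weinberg_k = sn$weinberg_k),
    foot_right = synthesize_foot_gyro(
      truth, "right", sn$fs_imu, mk_noise(sn$foot_noise, derive_seed(seed, 3)),
      weinberg_k = sn$weinberg_k),
    lumbar = synthesize_lumbar_accel(
      truth, sn$fs_imu, mk_noise(sn$lumbar_noise, derive_seed(seed, 4)),
      pendulum_length = config$analysis$pendulum_length,
      event_jitter_sd = jit,
      to_jitter_sd = if (noiseless) 0 else sn$lumbar_to_jitter_sd,
      to_time_bias = if (noiseless) 0 else sn$lumbar_to_bias),
    skeleton = synthesize_skeleton(
      truth, sn$fps, sn$clutter, mk_noise(sn$kinect_noise, derive_seed(seed, 5))))
}

# Walking-bout mask from a merged event list: windows split where the gap
# between consecutive events exceeds `gap` (turns are event-free).
bouts_from_events <- function(times, gap = 1.2, margin = 0.1) {
  times <- sort(times)
  if (!length(times)) return(data.frame(start = numeric(0), end = numeric(0)))
  brk <- which(diff(times) > gap)
  starts <- times[c(1, brk + 1)]
  ends <- times[c(brk, length(times))]
  data.frame(start = starts - margin, end = ends + margin)
}

# Attach step/stride lengths (meters) to a stride table. `steps` has
# columns time (end heel strike), foot, length. When `strides_df` is NULL
# the stride length is the sum of the two step lengths inside the stride.
attach_lengths <- function(strides, steps, strides_df = NULL, tol = 0.06) {
  if (!nrow(strides)) {
    strides$step_length <- numeric(0); strides$stride_length <- numeric(0)
    return(strides)
  }
  own_step <- function(f, tend) {
    j <- which(steps$foot == f & abs(steps$time - tend) < tol)
    if (length(j)) steps$length[j[1]] else NA_real_
  }
  contra_step <- function(f, t0, t1) {
    j <- which(steps$foot != f & steps$time > t0 & steps$time < t1 + tol)
    if (length(j)) steps$length[j[1]] else NA_real_
  }
  strides$step_length <- mapply(own_step, strides$foot, strides$t_end)
  if (is.null(strides_df)) {
    strides$stride_length <- strides$step_length +
      mapply(contra_step, strides$foot, strides$t_start, strides$t_end)
  } else {
    strides$stride_length <- mapply(function(f, tend) {
      j <- which(strides_df$foot == f & abs(strides_df$time - tend) < tol)
      if (length(j)) strides_df$length[j[1]] else NA_real_
    }, strides$foot, strides$t_end)
  }
  strides
}

# Merge detected heel strikes of both feet into step windows (consecutive
# opposite-foot heel strikes separated by less than `max_step`).
step_windows_from_series <- function(evL, evR, max_step = 1.0) {
  hs <- rbind(data.frame(time = evL$hs, foot = rep("left", length(evL$hs))),
              data.frame(time = evR$hs, foot = rep("right", length(evR$hs))))
  hs <- hs[order(hs$time), ]
  if (nrow(hs) < 2) return(data.frame(t0 = numeric(0), t1 = numeric(0),
                                      foot = character(0)))
  ok <- hs$foot[-1] != hs$foot[-nrow(hs)] & diff(hs$time) < max_step
  data.frame(t0 = hs$time[-nrow(hs)][ok], t1 = hs$time[-1][ok],
             foot = hs$foot[-1][ok])
}

analyze_foot <- function(trial, config) {
  an <- config$analysis
  res <- list()
  segs <- list()
  for (f in c("left", "right")) {
    rec <- trial[[paste0("foot_", f)]]
    filt <- preprocess_foot_gyro(rec$gyro[, "gy"], rec$fs, an$foot_highpass_hz,
                                 an$foot_lowpass_hz, an$fir_taps)
    res[[f]] <- detect_foot_events(filt, rec$fs, foot = f, t0 = rec$t[1])
  }
  mask <- bouts_from_events(c(res$left$hs, res$left$to, res$right$hs,
                              res$right$to), an$bout_gap)
  strides <- temporal_markers(res$left, res$right, mask = mask,
                              max_stride_time = an$max_stride_time)
  # Weinberg lengths: quartic acceleration-range roots per step/stride,
  # calibrated on the first bout against the reference distance
  sw <- step_windows_from_series(res$left, res$right)
  root_of <- function(f, t0, t1) {
    rec <- trial[[paste0("foot_", f)]]
    j <- which(rec$t >= t0 & rec$t <= t1)
    if (length(j) < 4) return(NA_real_)
    weinberg_root(rec$accel[j, "ax"], rec$accel[j, "az"],
                  rec$gyro[j, "gy"], rec$fs)
  }
  steps <- NULL
  if (nrow(sw)) {
    sw$root <- mapply(root_of, sw$foot, sw$t0, sw$t1)
    truth <- trial$truth
    cal <- sw$t1 <= mask$end[1] + 1e-6
    d_cal <- sum(truth$step_length[truth$pass == 1], na.rm = TRUE)
    K <- if (sum(cal, na.rm = TRUE) >= 3 && d_cal > 0)
      calibrate_K(sw$root[cal & !is.na(sw$root)], d_cal) else NA_real_
    if (!is.na(K)) steps <- data.frame(time = sw$t1, foot = sw$foot,
                                       length = K * sw$root)
    # stride constant: same procedure over per-foot stride windows
    stw <- do.call(rbind, lapply(c("left", "right"), function(f) {
      ev <- res[[f]]
      if (length(ev$hs) < 2) return(NULL)
      ok <- diff(ev$hs) < an$max_stride_time
      data.frame(t0 = ev$hs[-length(ev$hs)][ok], t1 = ev$hs[-1][ok], foot = f)
    }))
    strides_df <- NULL
    if (!is.null(stw) && nrow(stw)) {
      stw$root <- mapply(root_of, stw$foot, stw$t0, stw$t1)
      calS <- stw$t1 <= mask$end[1] + 1e-6 & !is.na(stw$root)
      d_str <- sum(vapply(c("left", "right"), function(f) {
        hs <- truth[truth$foot == f & truth$kind == "HS" & truth$pass == 1, ]
        if (nrow(hs) < 2) 0 else max(hs$position) - min(hs$position)
      }, numeric(1)))
      if (sum(calS) >= 3 && d_str > 0) {
        Ks <- calibrate_K(stw$root[calS], d_str)
        strides_df <- data.frame(time = stw$t1, foot = stw$foot,
                                 length = Ks * stw$root)
      }
    }
    strides <- attach_lengths(strides, steps, strides_df)
  }
  list(events = res, strides = strides)
}

analyze_lumbar <- function(trial, config) {
  an <- config$analysis
  rec <- trial$lumbar
  pre <- preprocess_lumbar(rec$accel[, "az"], rec$fs, an$lumbar_lowpass_hz)
  cfg <- cwt_config(scale = an$cwt$scale, scale_rule = an$cwt$scale_rule,
                    sign = an$cwt$sign)
  dif <- integrate_then_cwt_differentiate(pre, rec$fs, cfg)
  first_side <- {
    hs1 <- trial$truth[trial$truth$kind == "HS", ]
    if (nrow(hs1)) hs1$foot[1] else "right"
  }
  ev <- detect_lumbar_events(dif, rec$fs, first_side = first_side,
                             bout_gap = an$bout_gap, t0 = rec$t[1])
  mask <- bouts_from_events(c(ev$left$hs, ev$left$to, ev$right$hs,
                              ev$right$to), config$analysis$bout_gap)
  strides <- temporal_markers(ev$left, ev$right, mask = mask,
                              max_stride_time = an$max_stride_time)
  sw <- step_windows_from_series(ev$left, ev$right)
  steps <- NULL
  if (nrow(sw)) {
    l <- an$pendulum_length
    sw$length <- vapply(seq_len(nrow(sw)), function(i) {
      h <- tryCatch(step_vertical_displacement(rec$accel[, "ax"], rec$fs,
                                               c(sw$t0[i], sw$t1[i]),
                                               t_start = rec$t[1]),
                    error = function(e) NA_real_)
      if (is.na(h) || h >= 2 * l) return(NA_real_)
      pendulum_step_length(h, l)
    }, numeric(1))
    steps <- data.frame(time = sw$t1, foot = sw$foot, length = sw$length)
    strides <- attach_lengths(strides, steps)
  }
  list(events = ev, strides = strides)
}

analyze_kinect <- function(trial, config) {
  an <- config$analysis
  rec <- trial$skeleton
  fps <- attr(rec, "fps")
  if (is.null(fps)) fps <- 30
  track <- select_participant(rec, walkway_gate = an$gate)
  L <- resample_joint(track, "left_ankle", fps)
  R <- resample_joint(track, "right_ankle", fps)
  zL <- filter_joint_signal(L$z, fps, an$kinect_cutoff_hz)
  zR <- filter_joint_signal(R$z, fps, an$kinect_cutoff_hz)
  t <- L$t
  # body progression: ankle-mean depth smoothed below the step frequency,
  # so the velocity is steady within a pass and near zero in the turn
  body <- sos_filtfilt(butter_sos(2, 0.5, fps, type = "low"), (zL + zR) / 2)
  vz <- num_gradient(body) * fps
  thr <- 0.5 * stats::quantile(abs(vz), 0.8)
  moving <- abs(vz) > max(thr, 0.1)
  r <- rle(moving)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  pass_runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  pass_runs <- pass_runs[(pass_runs$i1 - pass_runs$i0) / fps >= 1.5, , drop = FALSE]
  # widen each pass so the boundary toe-off/heel-strike lobes are inside
  pass_runs$i0 <- pmax(1L, pass_runs$i0 - as.integer(0.4 * fps))
  pass_runs$i1 <- pmin(length(t), pass_runs$i1 + as.integer(0.4 * fps))
  evL_all <- list(); evR_all <- list(); mask <- NULL
  for (k in seq_len(nrow(pass_runs))) {
    j <- seq(pass_runs$i0[k], pass_runs$i1[k])
    dirn <- sign(mean(vz[j]))
    aL <- ankle_acceleration(zL[j], fps)
    aR <- ankle_acceleration(zR[j], fps)
    ev <- detect_kinect_events(aL, aR, fps, direction_sign = dirn,
                               t0 = t[j[1]])
    evL_all[[k]] <- ev$left; evR_all[[k]] <- ev$right
    mask <- rbind(mask, data.frame(start = t[j[1]] - 0.05,
                                   end = t[j[length(j)]] + 0.05))
  }
  cat_series <- function(lst, foot) {
    hs <- sort(unlist(lapply(lst, `[[`, "hs")))
    to <- sort(unlist(lapply(lst, `[[`, "to")))
    event_series(foot, hs, to, "kinect")
  }
  evL <- cat_series(evL_all, "left")
  evR <- cat_series(evR_all, "right")
  strides <- temporal_markers(evL, evR, mask = mask,
                              max_stride_time = an$max_stride_time)
  len <- kinect_lengths(zL, zR, t, evL, evR)
  strides <- attach_lengths(strides, len$steps, len$strides)
  list(events = list(left = evL, right = evR), strides = strides,
       lengths = len, track = track)
}

analyze_reference <- function(trial, config) {
  truth <- trial$truth
  evL <- reference_events(truth, "left")
  evR <- reference_events(truth, "right")
  pw <- attr(truth, "pass_windows")
  mask <- data.frame(start = pw$start - 0.05, end = pw$end + 0.05)
  strides <- temporal_markers(evL, evR, mask = mask,
                              max_stride_time = config$analysis$max_stride_time)
  hs <- truth[truth$kind == "HS" & !is.na(truth$step_length), ]
  steps <- data.frame(time = hs$time, foot = hs$foot, length = hs$step_length)
  strides <- attach_lengths(strides, steps)
  list(events = list(left = evL, right = evR), strides = strides)
}

#' Run all detection pipelines and marker extraction on one trial
#'
#' @param trial output of [simulate_trial()] (or equivalent read from
#'   disk): `truth`, `foot_left`, `foot_right`, `lumbar`, `skeleton`.
#'   Missing streams are skipped with a warning.
#' @param config a [default_config()] list.
#' @param task trial label for the summaries.
#' @return list by modality (`reference`, `foot`, `lumbar`, `kinect`),
#'   each with `events`, `strides`, and `summary` (a [trial_summary()]).
#' @export
analyze_trial <- function(trial, config = default_config(),
                          task = "single_task") {
  out <- list(reference = analyze_reference(trial, config))
  if (!is.null(trial$foot_left) && !is.null(trial$foot_right))
    out$foot <- analyze_foot(trial, config)
  else warning("foot streams missing: foot modality skipped")
  if (!is.null(trial$lumbar)) out$lumbar <- analyze_lumbar(trial, config)
  else warning("lumbar stream missing: lumbar modality skipped")
  if (!is.null(trial$skeleton)) out$kinect <- analyze_kinect(trial, config)
  else warning("skeleton stream missing: kinect modality skipped")
  for (m in names(out)) {
    out[[m]]$summary <- tryCatch(trial_summary(out[[m]]$strides, task = task),
                                 error = function(e) NULL)
  }
  out
}

#' Match detected events against ground truth
#'
#' Greedy nearest matching of detected to true events within a tolerance;
#' reports sensitivity (matched / true), precision (matched / detected)
#' and the matched timing errors.
#'
#' @param truth a `gait_events` train.
#' @param detected list with per-foot [event_series()] (`left`, `right`).
#' @param tol matching tolerance, seconds.
#' @return list with `sensitivity`, `precision`, `errors` (seconds), and
#'   per-kind counts.
#' @export
event_recovery <- function(truth, detected, tol = 0.03) {
  n_true <- 0L; n_det <- 0L; n_match <- 0L; errs <- numeric(0)
  for (f in c("left", "right")) for (k in c("HS", "TO")) {
    tt <- truth$time[truth$foot == f & truth$kind == k]
    dd <- if (k == "HS") detected[[f]]$hs else detected[[f]]$to
    n_true <- n_true + length(tt); n_det <- n_det + length(dd)
    used <- rep(FALSE, length(dd))
    for (x in tt) {
      if (!length(dd)) next
      j <- which(!used & abs(dd - x) <= tol)
      if (length(j)) {
        j <- j[which.min(abs(dd[j] - x))]
        used[j] <- TRUE
        n_match <- n_match + 1L
        errs <- c(errs, dd[j] - x)
      }
    }
  }
  list(sensitivity = if (n_true) n_match / n_true else NA_real_,
       precision = if (n_det) n_match / n_det else NA_real_,
       errors = errs, n_true = n_true, n_detected = n_det)
}

#' Simulate and analyze a full cohort, with agreement against reference
#'
#' For each subject, simulates one trial per task, runs all pipelines,
#' aggregates subject-trial marker means, and computes per-marker
#' agreement of each modality against the reference events.
#'
#' @param config a [default_config()] list.
#' @param seed cohort RNG seed.
#' @param tasks task conditions to simulate.
#' @param noiseless zero all sensor noise.
#' @return list by task of [agreement_report()] objects; attribute
#'   `summaries` holds the per-subject trial summaries.
#' @export
run_cohort <- function(config = default_config(), seed = 1,
                       tasks = c("single_task", "dual_task"),
                       noiseless = FALSE) {
  reports <- list()
  all_sum <- list()
  for (task in tasks) {
    toff <- match(task, c("single_task", "dual_task", "practice"))
    subj <- vector("list", config$cohort$n_subjects)
    for (s in seq_len(config$cohort$n_subjects)) {
      pr <- subject_profile(config, task, derive_seed(seed, s, toff, 1))
      trial <- simulate_trial(pr, config, derive_seed(seed, s, toff, 2),
                              noiseless = noiseless)
      subj[[s]] <- analyze_trial(trial, config, task = task)
    }
    all_sum[[task]] <- subj
    get_mean <- function(res, marker) {
      sm <- res$summary
      if (is.null(sm)) return(NA_real_)
      j <- which(sm$marker == marker)
      if (length(j)) sm$mean[j] else NA_real_
    }
    markers <- unique(unlist(lapply(subj, function(x)
      if (!is.null(x$reference$summary)) x$reference$summary$marker)))
    samples <- list()
    for (mod in setdiff(names(subj[[1]]), "reference")) {
      lst <- list()
      for (mk in markers) {
        ref <- vapply(subj, function(x) get_mean(x$reference, mk), numeric(1))
        tst <- vapply(subj, function(x) get_mean(x[[mod]], mk), numeric(1))
        ok <- !is.na(ref) & !is.na(tst)
        if (sum(ok) >= 2) {
          u <- subj[[1]]$reference$summary
          lst[[mk]] <- paired_marker_sample(mk, ref[ok], tst[ok],
                                            units = u$units[u$marker == mk][1])
        }
      }
      samples[[mod]] <- lst
    }
    reports[[task]] <- agreement_report(samples, task = task)
  }
  structure(reports, summaries = all_sum)
}

#' Mean MAEP over the temporal markers, per modality
#'
#' The qualitative cross-modality comparison statistic: foot-mounted
#' sensing is expected to show the smallest mean temporal MAEP, the
#' lumbar sensor the largest.
#'
#' @param report an [agreement_report()].
#' @return named numeric vector of mean MAEP (%) by modality.
#' @export
temporal_maep <- function(report) {
  temporal <- c("step_time", "stride_time", "stance_time", "swing_time",
                "single_support", "double_support")
  d <- report$results[report$results$marker %in% temporal, ]
  tapply(d$maep, d$modality, mean, na.rm = TRUE)
}
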