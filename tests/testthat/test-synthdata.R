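test_that("zero-variance profiles reproduce their construction exactly", {
  pr <- zero_var_profile(stride_time_mean = 1.08, stance_fraction = 0.657,
                         double_support_fraction = 0.222, n_passes = 1)
  ev <- generate_event_sequence(pr, seed = 3)
  hsL <- ev$time[ev$foot == "left" & ev$kind == "HS"]
  expect_true(all(abs(diff(hsL) - 1.08) < 1e-9))
  toL <- ev$time[ev$foot == "left" & ev$kind == "TO"]
  # stance of the initiating foot = stance_fraction x stride
  stance <- toL[2] - hsL[1]
  expect_equal(stance, 0.657 * 1.08, tolerance = 1e-9)   # 0.7096 s
  expect_equal(1.08 - stance, (1 - 0.657) * 1.08, tolerance = 1e-9)  # 0.3704 s
})

test_that("event trains satisfy their structural invariants across seeds", {
  for (seed in 1:8) {
    pr <- gait_profile(stride_time_sd = 0.03, step_length_sd = 0.03,
                       n_passes = 2)
    ev <- generate_event_sequence(pr, seed = seed)
    expect_silent(validate_gait_events(ev))
    # cumulative step lengths never exceed the path length, per pass
    for (p in unique(ev$pass)) {
      d <- ev[ev$pass == p & !is.na(ev$step_length), ]
      expect_lte(sum(d$step_length), pr$path_length)
    }
  }
})

test_that("generation is deterministic in the seed", {
  pr <- gait_profile()
  expect_identical(generate_event_sequence(pr, seed = 7),
                   generate_event_sequence(pr, seed = 7))
  a <- generate_event_sequence(pr, seed = 7)
  b <- generate_event_sequence(pr, seed = 8)
  expect_false(isTRUE(all.equal(a$time, b$time)))
})

test_that("impossible geometry and invalid profiles are rejected", {
  expect_error(gait_profile(stance_fraction = 0.5,
                            double_support_fraction = 0.6))
  expect_error(gait_profile(stride_time_mean = -1))
  pr <- gait_profile(step_length_mean = 4, path_length = 7)
  expect_error(generate_event_sequence(pr), "path_length")
})

test_that("trigger synthesis is sample-exact", {
  s <- synthesize_trigger(list(c(10, 20)), fs = 120, total_duration = 30)
  expect_equal(sum(s$level == 0), 1200)
  expect_true(all(s$level %in% c(0, 5)))
  expect_true(all(synthesize_trigger(list(), 120, 30)$level == 5))
  expect_true(all(synthesize_trigger(list(c(0, 30)), 120, 30)$level == 0))
  expect_error(synthesize_trigger(list(c(0, 10), c(5, 15)), 120, 30),
               "overlap")
})

test_that("foot gyro stream has event lobes at ground truth and exact length", {
  pr <- zero_var_profile(n_passes = 1)
  ev <- generate_event_sequence(pr, seed = 1)
  rec <- synthesize_foot_gyro(ev, "left", fs = 128, duration = 10)
  expect_length(rec$t, 1280)
  # noiseless: per-event global minima within one sample of each true HS
  hs <- ev$time[ev$foot == "left" & ev$kind == "HS"]
  for (h in hs[hs < 9.5]) {
    j <- which(rec$t > h - 0.2 & rec$t < h + 0.2)
    expect_lt(abs(rec$t[j[which.min(rec$gyro[j, "gy"])]] - h), 1 / 128 + 1e-9)
  }
})

test_that("drift is rejected by the high-pass stage but corrupts raw extrema", {
  pr <- zero_var_profile(n_passes = 1)
  ev <- generate_event_sequence(pr, seed = 2)
  noise <- sensor_noise(gaussian_sd = 0, drift_amplitude = 5,
                        drift_period = 30, seed = 1)
  rec <- synthesize_foot_gyro(ev, "left", 128, noise)
  raw_min <- rec$t[which.min(rec$gyro[, "gy"])]
  hs <- ev$time[ev$foot == "left" & ev$kind == "HS"]
  # raw global minimum is dragged away from the nearest heel strike lobe
  filt <- preprocess_foot_gyro(rec$gyro[, "gy"], 128)
  f_min <- rec$t[which.min(filt)]
  expect_lt(min(abs(hs - f_min)), 1.5 / 128)
  events <- detect_foot_events(filt, 128, "left")
  r <- event_recovery(ev, list(left = events,
                               right = event_series("right", numeric(0),
                                                    numeric(0), "foot_imu")),
                      tol = 0.015)
  hs_l <- sum(ev$foot == "left")
  expect_gte(r$sensitivity * r$n_true / hs_l, 0.99)
})

test_that("lumbar stream embeds the pendulum vertical excursion", {
  # inversion: step length 0.6245 m at l = 1 m embeds h = 0.05 m
  h <- 1 - sqrt(1 - 0.6245^2 / 4)
  expect_equal(h, 0.05, tolerance = 1e-4)
  pr <- zero_var_profile(step_length_mean = 0.6245, n_passes = 1)
  ev <- generate_event_sequence(pr, seed = 1)
  rec <- synthesize_lumbar_accel(ev, 128, pendulum_length = 1.0)
  hs <- ev$time[ev$kind == "HS"]
  hrec <- step_vertical_displacement(rec$accel[, "ax"], 128,
                                     c(hs[3], hs[4]))
  expect_equal(hrec, 0.05, tolerance = 0.05)
  # impossible geometry rejected
  expect_error(synthesize_lumbar_accel(ev, 128, pendulum_length = 0.25),
               "pendulum")
})

test_that("skeleton stream carries one persistent participant plus clutter", {
  pr <- zero_var_profile()
  ev <- generate_event_sequence(pr, seed = 4)
  s0 <- synthesize_skeleton(ev, fps = 30, clutter = 0)
  expect_length(unique(s0$body_id), 1)
  s2 <- synthesize_skeleton(ev, fps = 30, clutter = 2)
  ids <- unique(s2$body_id)
  expect_gte(length(ids), 3)
  times <- unique(s2$time)
  cover <- vapply(ids, function(id)
    length(unique(s2$time[s2$body_id == id])) / length(times), numeric(1))
  expect_equal(sum(cover >= 0.95), 1)
  expect_error(synthesize_skeleton(ev, fps = 31), "fps")
})

test_that("outbound ankle depth decreases by the stride length between heel strikes", {
  pr <- zero_var_profile()
  ev <- generate_event_sequence(pr, seed = 5)
  sk <- synthesize_skeleton(ev, fps = 30, clutter = 0)
  ra <- sk[sk$joint == "right_ankle", ]
  hsR <- ev[ev$foot == "right" & ev$kind == "HS" & ev$pass == 1, ]
  z_at <- vapply(hsR$time, function(w) ra$z[which.min(abs(ra$time - w))],
                 numeric(1))
  stride <- 2 * pr$step_length_mean
  expect_true(all(abs(diff(z_at) + stride) < 0.01))
})
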