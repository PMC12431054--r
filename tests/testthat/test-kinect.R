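test_that("participant selection survives clutter and id permutation", {
  pr <- zero_var_profile()
  ev <- generate_event_sequence(pr, seed = 21)
  sk <- synthesize_skeleton(ev, fps = 30, clutter = 2,
                            noise = sensor_noise(seed = 3))
  tr <- select_participant(sk)
  expect_equal(tr$body_id, attr(sk, "participant_id"))
  # permute the clutter ids: the same participant must win
  sk2 <- sk
  ids <- setdiff(unique(sk2$body_id), tr$body_id)
  remap <- stats::setNames(sample(ids), ids)
  sk2$body_id[sk2$body_id %in% ids] <- remap[as.character(
    sk2$body_id[sk2$body_id %in% ids])]
  expect_equal(select_participant(sk2)$body_id, tr$body_id)
  # single body
  sk0 <- synthesize_skeleton(ev, fps = 30, clutter = 0)
  t0 <- select_participant(sk0)
  expect_equal(t0$coverage, 1)
  expect_error(select_participant(sk0[0, ]), "empty")
  # everyone outside the gate
  expect_error(select_participant(sk0, walkway_gate = c(5, 6)), "gate")
})

test_that("joint filtering and second gradient behave analytically", {
  fps <- 30
  t <- (0:299) / fps
  expect_equal(filter_joint_signal(rep(2, 300), fps), rep(2, 300),
               tolerance = 1e-6)
  expect_error(filter_joint_signal(t, 6), "rate")
  # constant acceleration: x = a t^2 / 2 recovers a in the interior
  a_true <- 1.7
  acc <- ankle_acceleration(a_true * t^2 / 2, fps)
  expect_equal(acc[10:290], rep(a_true, 281), tolerance = 1e-6)
  expect_equal(max(abs(ankle_acceleration(3 * t, fps))), 0, tolerance = 1e-9)
  s <- sin(2 * pi * 1.5 * t)
  acc_s <- ankle_acceleration(s, fps)
  expect_equal(acc_s[30:270], -(2 * pi * 1.5)^2 * s[30:270],
               tolerance = 0.05 * (2 * pi * 1.5)^2)
  expect_error(ankle_acceleration(1:4, fps), "short")
})

test_that("noiseless kinect detection recovers events within 1.5 frames", {
  cfg <- default_config()
  pr <- zero_var_profile()
  tr <- simulate_trial(pr, cfg, seed = 22, noiseless = TRUE)
  ka <- multigait:::analyze_kinect(tr, cfg)
  r <- event_recovery(tr$truth, ka$events, tol = 1.5 / 30)
  expect_gte(r$sensitivity, 0.9)
  expect_gte(r$precision, 0.9)
})

test_that("flipping the direction sign swaps heel strikes and toe-offs", {
  fps <- 30
  t <- (0:299) / fps
  acc <- sin(2 * pi * 1 * t)
  a <- detect_kinect_events(acc, acc, fps, direction_sign = -1)
  b <- detect_kinect_events(acc, acc, fps, direction_sign = +1)
  expect_equal(a$left$hs, b$left$to)
  expect_equal(a$left$to, b$left$hs)
  z <- detect_kinect_events(rep(0, 300), rep(0, 300), fps, -1)
  expect_true(z$left$empty_warning)
})

test_that("depth differences at heel strikes give step and stride lengths", {
  # hand arithmetic from ankle depths
  t <- seq(0, 5, by = 1 / 30)
  zL <- rep(3.72, length(t)); zR <- rep(3.10, length(t))
  zR[t > 2] <- 1.86
  eL <- event_series("left", 1.0, numeric(0), "kinect")
  eR <- event_series("right", c(1.5, 3.0), numeric(0), "kinect")
  len <- kinect_lengths(zL, zR, t, eL, eR)
  expect_equal(len$steps$length[1], 0.62, tolerance = 1e-9)
  expect_equal(len$strides$length, 3.10 - 1.86, tolerance = 1e-9)
  expect_warning(kinect_lengths(zL, zR, t,
                                event_series("left", 10, numeric(0), "kinect"),
                                eR), "span")
})

test_that("synthetic noiseless scene yields lengths within 2 cm of truth", {
  cfg <- default_config()
  pr <- zero_var_profile()
  tr <- simulate_trial(pr, cfg, seed = 23, noiseless = TRUE)
  ka <- multigait:::analyze_kinect(tr, cfg)
  st <- ka$strides
  expect_gt(nrow(st), 8)
  expect_lt(abs(mean(st$stride_length, na.rm = TRUE) -
                  2 * pr$step_length_mean), 0.02)
  expect_lt(abs(mean(st$step_length, na.rm = TRUE) - pr$step_length_mean), 0.02)
})

test_that("lengths are direction-invariant on symmetric gait", {
  cfg <- default_config()
  pr <- zero_var_profile()
  tr <- simulate_trial(pr, cfg, seed = 24, noiseless = TRUE)
  ka <- multigait:::analyze_kinect(tr, cfg)
  pw <- attr(tr$truth, "pass_windows")
  st <- ka$strides
  out <- st$stride_length[st$t_end <= pw$end[1]]
  ret <- st$stride_length[st$t_start >= pw$start[2]]
  expect_lt(abs(mean(out, na.rm = TRUE) - mean(ret, na.rm = TRUE)), 0.02)
})
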