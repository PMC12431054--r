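test_that("the hand-traced stride reproduces every temporal marker", {
  evL <- event_series("left", hs_times = c(0.00, 1.08),
                      to_times = 0.66, modality = "reference")
  evR <- event_series("right", hs_times = c(0.54, 1.62),
                      to_times = c(0.12, 1.20), modality = "reference")
  st <- temporal_markers(evL, evR)
  r <- st[st$foot == "right", ]
  expect_equal(nrow(r), 1)
  expect_equal(r$step_time, 0.54)
  expect_equal(r$stride_time, 1.08)
  expect_equal(r$stance_time, 0.66)
  expect_equal(r$swing_time, 0.42)
  expect_equal(r$ds_initial, 0.12)
  expect_equal(r$ds_terminal, 0.12)
  expect_equal(r$ds_total, 0.24)
  expect_equal(r$single_support, 0.42)
})

test_that("symmetric zero-variance gait gives identical left/right means", {
  pr <- zero_var_profile()
  ev <- generate_event_sequence(pr, seed = 31)
  st <- temporal_markers(reference_events(ev, "left"),
                         reference_events(ev, "right"),
                         mask = attr(ev, "pass_windows"))
  for (m in c("stride_time", "stance_time", "swing_time", "ds_total")) {
    expect_equal(mean(st[[m]][st$foot == "left"]),
                 mean(st[[m]][st$foot == "right"]), tolerance = 1e-9)
  }
})

test_that("insufficient events yield an empty stride table", {
  evL <- event_series("left", 0.0, numeric(0), "reference")
  evR <- event_series("right", 0.54, numeric(0), "reference")
  st <- temporal_markers(evL, evR)
  expect_equal(nrow(st), 0)
})

test_that("markers agree with the brute-force interval oracle on random trains", {
  for (seed in 1:40) {
    ev <- random_event_train(n_strides = sample(4:10, 1), seed = seed)
    st <- temporal_markers(events_from_train(ev, "left"),
                           events_from_train(ev, "right"))
    or <- oracle_markers(ev)
    expect_equal(nrow(st), nrow(or))
    for (m in c("step_time", "stride_time", "stance_time", "swing_time",
                "single_support", "ds_initial", "ds_terminal", "ds_total")) {
      expect_equal(st[[m]], or[[m]], tolerance = 1e-9)
    }
    # conservation identities, per stride, to two sample periods
    tol <- 2 / 128
    expect_true(all(abs(st$stance_time + st$swing_time - st$stride_time) <= tol))
    expect_true(all(abs(st$ds_total - st$ds_initial - st$ds_terminal) <= tol))
    expect_true(all(abs(st$stance_time - st$single_support - st$ds_total) <= tol))
  }
})

test_that("Weinberg length follows the quartic-root formula", {
  # a segment whose aZ range is exactly 16 m/s^2 with zero pitch
  fs <- 128
  az <- 9.81 + seq(-8, 8, length.out = 128)
  gy <- rep(0, 128); ax <- rep(0, 128)
  expect_equal(weinberg_length(ax, az, gy, fs, K = 0.5), 0.5 * 16^0.25,
               tolerance = 1e-9)  # exactly 1.0 m
  expect_warning(out <- weinberg_length(rep(0, 10), rep(9.81, 10),
                                        rep(0, 10), fs, K = 0.5), "flat")
  expect_equal(out, 0)
})

test_that("calibration returns distance over summed roots", {
  expect_equal(calibrate_K(c(2, 2, 2), 3.0), 0.5)
  expect_error(calibrate_K(c(2), 3.0), "3 calibration")
  expect_error(calibrate_K(c(0, 0, 0), 3.0), "degenerate")
  # calibrated K reproduces per-step lengths with zero mean bias
  roots <- runif(8, 1.8, 2.2)
  K <- calibrate_K(roots, sum(roots) * 0.31)
  expect_equal(mean(K * roots - 0.31 * roots), 0, tolerance = 1e-12)
})

test_that("K calibrated on one pass transfers to the other within 8%", {
  cfg <- default_config()
  pr <- gait_profile(stride_time_sd = 0.02, step_length_sd = 0.02)
  tr <- simulate_trial(pr, cfg, seed = 33, noiseless = TRUE)
  fa <- multigait:::analyze_foot(tr, cfg)
  pw <- attr(tr$truth, "pass_windows")
  st <- fa$strides
  pass2 <- st[st$t_start >= pw$start[2], ]
  expect_gt(nrow(pass2), 3)
  expect_lt(abs(mean(pass2$step_length, na.rm = TRUE) - pr$step_length_mean) /
              pr$step_length_mean, 0.08)
})

test_that("pendulum step length evaluates the closed form and guards the domain", {
  expect_equal(pendulum_step_length(0, 1), 0)
  expect_equal(pendulum_step_length(0.05, 1.0), 2 * sqrt(0.0975),
               tolerance = 1e-9)
  expect_equal(pendulum_step_length(0.05, 1.0), 0.6245, tolerance = 1e-4)
  expect_error(pendulum_step_length(2.1, 1.0), "imaginary")
  # the step length peaks at h = l (step = 2l) and returns to zero as
  # h approaches the domain boundary 2l
  expect_equal(pendulum_step_length(1, 1), 2)
  expect_lt(pendulum_step_length(2 - 1e-8, 1), 1e-3)
})

test_that("macro markers follow their defining arithmetic", {
  st <- data.frame(foot = rep(c("left", "right"), 5),
                   t_start = 1:10, t_end = 2:11,
                   step_time = 0.54, stride_time = 1.08, stance_time = 0.71,
                   swing_time = 0.37, single_support = 0.37,
                   ds_initial = 0.17, ds_terminal = 0.17, ds_total = 0.34,
                   step_length = 0.648, stride_length = 1.2960)
  class(st) <- c("stride_table", "data.frame")
  ts <- trial_summary(st)
  expect_equal(ts$mean[ts$marker == "cadence"], 111.1111, tolerance = 1e-4)
  expect_equal(ts$mean[ts$marker == "velocity"], 120.0, tolerance = 1e-9)
  expect_equal(ts$mean[ts$marker == "stride_velocity"], 120.0, tolerance = 1e-9)
  # halving stride times at fixed lengths doubles cadence and velocity
  st2 <- st; st2$stride_time <- st$stride_time / 2
  ts2 <- trial_summary(st2)
  expect_equal(ts2$mean[ts2$marker == "cadence"],
               2 * ts$mean[ts$marker == "cadence"], tolerance = 1e-9)
  expect_equal(ts2$mean[ts2$marker == "velocity"],
               2 * ts$mean[ts$marker == "velocity"], tolerance = 1e-9)
  # one stride: SDs reported as zero
  one <- trial_summary(st[1, ])
  expect_true(all(one$sd == 0))
  expect_error(trial_summary(st[0, ]), "strides")
})

test_that("reference events reproduce profile values exactly at zero variance", {
  pr <- zero_var_profile(step_length_mean = 0.6245)
  ev <- generate_event_sequence(pr, seed = 35)
  ref <- multigait:::analyze_reference(list(truth = ev), default_config())
  sm <- trial_summary(ref$strides)
  g <- function(m) sm$mean[sm$marker == m]
  expect_equal(g("stride_time"), 1.08, tolerance = 1e-9)
  expect_equal(g("step_time"), 0.54, tolerance = 1e-9)
  expect_equal(g("stance_time"), 0.657 * 1.08, tolerance = 1e-9)
  expect_equal(g("step_length"), 62.45, tolerance = 1e-9)
  expect_equal(g("stride_length"), 124.90, tolerance = 1e-9)
})
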