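fs <- 128

test_that("lumbar preprocessing removes linear trends and high frequencies", {
  t <- (0:(10 * fs - 1)) / fs
  expect_lt(max(abs(preprocess_lumbar(3 + 0.2 * t, fs))), 1e-6)
  y20 <- preprocess_lumbar(sin(2 * pi * 20 * t), fs)
  expect_lte(max(abs(y20[(2 * fs):(8 * fs)])), 0.26)
  # least-squares detrending of a finite sine leaves a small linear
  # leakage at the ends; the passband gain is read from the central half
  y1 <- preprocess_lumbar(sin(2 * pi * 1 * t), fs)
  expect_equal(max(abs(y1[(3 * fs):(7 * fs)])), 1, tolerance = 0.03)
  expect_error(preprocess_lumbar(1:10, fs), "short")
})

test_that("integrate-then-differentiate acts as a smoothed identity", {
  t <- (0:(12 * fs - 1)) / fs
  f0 <- 1.8
  x <- sin(2 * pi * f0 * t)
  y <- integrate_then_cwt_differentiate(x, fs, cwt_config(scale = fs / (2 * f0)))
  mid <- (3 * fs):(9 * fs)
  # output stays a sinusoid at f0, in phase with the input
  cc <- stats::ccf(y[mid], x[mid], lag.max = round(fs / (4 * f0)), plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0, tolerance = 2)
  expect_equal(as.numeric(integrate_then_cwt_differentiate(rep(0, 6 * fs), fs,
                                                           cwt_config(35))),
               rep(0, 6 * fs))
  expect_error(integrate_then_cwt_differentiate(x[1:100], fs, cwt_config(35)),
               "scale")
})

test_that("an impulse reproduces the wavelet kernel around its location", {
  x <- rep(0, 6 * fs); x[3 * fs] <- 1
  xi <- multigait:::cumtrapz1(seq_along(x) / fs, x)
  y <- multigait:::cwt_gaus1(xi, 32)
  # the response is odd around the impulse and peaks at +/- sigma
  pk <- which.max(y)
  expect_equal(pk, 3 * fs + 4, tolerance = 2)
  trough <- which.min(y)
  expect_equal(pk - 3 * fs, -(trough - 3 * fs), tolerance = 2)
})

test_that("noiseless lumbar round-trip recovers events within 30 ms", {
  pr <- zero_var_profile()
  ev <- generate_event_sequence(pr, seed = 12)
  rec <- synthesize_lumbar_accel(ev, fs)
  pre <- preprocess_lumbar(rec$accel[, "az"], fs)
  dif <- integrate_then_cwt_differentiate(pre, fs,
                                          cwt_config(scale_rule = "from_step_frequency"))
  det <- detect_lumbar_events(dif, fs, first_side = "left")
  r <- event_recovery(ev, det, tol = 0.03)
  expect_gte(r$sensitivity, 0.95)
  expect_gte(r$precision, 0.95)
})

test_that("first-side choice only relabels the feet", {
  pr <- zero_var_profile()
  ev <- generate_event_sequence(pr, seed = 13)
  rec <- synthesize_lumbar_accel(ev, fs)
  dif <- integrate_then_cwt_differentiate(preprocess_lumbar(rec$accel[, "az"], fs),
                                          fs, cwt_config(35))
  a <- detect_lumbar_events(dif, fs, first_side = "left")
  b <- detect_lumbar_events(dif, fs, first_side = "right")
  expect_equal(a$left$hs, b$right$hs)
  expect_equal(a$right$to, b$left$to)
})

test_that("scale rule and fixed scale give the same event times within a sample", {
  pr <- zero_var_profile()
  ev <- generate_event_sequence(pr, seed = 14)
  rec <- synthesize_lumbar_accel(ev, fs)
  pre <- preprocess_lumbar(rec$accel[, "az"], fs)
  d1 <- integrate_then_cwt_differentiate(pre, fs,
                                         cwt_config(scale_rule = "from_step_frequency"))
  f_step <- 2 / pr$stride_time_mean
  d2 <- integrate_then_cwt_differentiate(pre, fs,
                                         cwt_config(scale = fs / (2 * f_step)))
  e1 <- detect_lumbar_events(d1, fs); e2 <- detect_lumbar_events(d2, fs)
  expect_length(e1$left$hs, length(e2$left$hs))
  expect_lte(max(abs(e1$left$hs - e2$left$hs)), 1 / fs + 1e-9)
})

test_that("step vertical displacement matches the closed-form double integral", {
  f0 <- 2; A <- 0.03
  t1 <- (0:(fs / f0)) / fs  # one full period of the f0 wave, inclusive
  a1 <- -A * (2 * pi * f0)^2 * sin(2 * pi * f0 * t1)
  h <- step_vertical_displacement(a1, fs, c(0, (length(a1) - 1) / fs))
  expect_equal(h, 2 * A, tolerance = 0.02)
  expect_equal(step_vertical_displacement(rep(0, 200), fs, c(0, 1)), 0)
  expect_error(step_vertical_displacement(rep(1, 200), fs, c(0, 0.01)),
               "3 samples")
})

test_that("pendulum step lengths from the recovered excursion stay within 10%", {
  pr <- zero_var_profile()
  ev <- generate_event_sequence(pr, seed = 15)
  rec <- synthesize_lumbar_accel(ev, fs, pendulum_length = 0.94)
  hs <- ev[ev$kind == "HS", ]
  rel_err <- c()
  for (i in seq_len(nrow(hs))[-1]) {
    if (hs$pass[i] != hs$pass[i - 1] || is.na(hs$step_length[i])) next
    h <- step_vertical_displacement(rec$accel[, "ax"], fs,
                                    c(hs$time[i - 1], hs$time[i]))
    sl <- pendulum_step_length(h, 0.94)
    rel_err <- c(rel_err, abs(sl - hs$step_length[i]) / hs$step_length[i])
  }
  expect_lte(mean(rel_err), 0.10)
})
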