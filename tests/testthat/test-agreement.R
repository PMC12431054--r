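test_that("MAE is the mean and SD of absolute paired differences", {
  s <- paired_marker_sample("x", c(1, 2, 3), c(1, 2, 3))
  expect_equal(mae_stats(s), list(mean = 0, sd = 0))
  s2 <- paired_marker_sample("x", c(1, 2, 3), c(2, 4, 3))
  m <- mae_stats(s2)
  expect_equal(m$mean, 1.0)
  expect_equal(m$sd, 1.0)
  big <- paired_marker_sample("x", c(1, 2, 3), c(1, 2, 3) + 100)
  expect_equal(mae_stats(big)$mean, 100)
  expect_error(paired_marker_sample("x", 1, 1), "2 pairs")
})

test_that("MAEP is scale-invariant and guards zero references", {
  s <- paired_marker_sample("x", c(100, 100), c(90, 110))
  expect_equal(maep(s), 10.0)
  expect_equal(maep(paired_marker_sample("x", c(1, 2), c(1, 2))), 0)
  s7 <- paired_marker_sample("x", 7 * c(100, 100), 7 * c(90, 110))
  expect_equal(maep(s7), 10.0)
  expect_error(maep(paired_marker_sample("x", c(0, 1), c(1, 1))), "zero")
})

test_that("Pearson agreement handles affine, inverted, and degenerate inputs", {
  x <- c(1, 3, 5, 7, 11)
  p <- pearson_agreement(paired_marker_sample("x", x, 2 * x + 1))
  expect_equal(p$r, 1, tolerance = 1e-12)
  expect_lt(p$p, 0.001)
  expect_equal(pearson_agreement(paired_marker_sample("x", x, -x))$r, -1,
               tolerance = 1e-12)
  expect_error(pearson_agreement(paired_marker_sample("x", x, rep(1, 5))),
               "variance")
  expect_error(pearson_agreement(paired_marker_sample("x", 1:2, 1:2)), "3")
})

test_that("simulated bivariate-normal correlation is recovered", {
  # E[r] at rho = 0.9, n = 20 is about 0.894 (small-sample bias)
  set.seed(99)
  rhat <- replicate(1000, {
    u <- rnorm(20); v <- rnorm(20)
    x <- u; y <- 0.9 * u + sqrt(1 - 0.81) * v
    pearson_agreement(paired_marker_sample("x", x, y))$r
  })
  expect_equal(mean(rhat), 0.894, tolerance = 0.02)
})

test_that("Bland-Altman bias and limits follow the normal model", {
  x <- c(1, 2, 3, 4)
  ba0 <- bland_altman(paired_marker_sample("x", x, x))
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_high - ba0$loa_low, 0)
  ba5 <- bland_altman(paired_marker_sample("x", x, x + 5))
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$loa_low, 5); expect_equal(ba5$loa_high, 5)
  set.seed(7)
  ref <- rnorm(10000, 10, 1)
  test <- ref + rnorm(10000, 2, 1)
  ba <- bland_altman(paired_marker_sample("x", ref, test))
  expect_equal(ba$bias, 2, tolerance = 0.03)
  expect_equal(ba$loa_low, 2 - 1.96, tolerance = 0.05)
  expect_equal(ba$loa_high, 2 + 1.96, tolerance = 0.05)
})

test_that("swapping reference and test negates bias and preserves MAE and |r|", {
  set.seed(8)
  ref <- rnorm(30, 100, 10); test <- ref + rnorm(30, 3, 2)
  a <- paired_marker_sample("x", ref, test)
  b <- paired_marker_sample("x", test, ref)
  expect_equal(bland_altman(a)$bias, -bland_altman(b)$bias)
  expect_equal(bland_altman(a)$loa_high, -bland_altman(b)$loa_low)
  expect_equal(mae_stats(a), mae_stats(b))
  expect_equal(abs(pearson_agreement(a)$r), abs(pearson_agreement(b)$r))
})

test_that("the agreement report emits the expected tables and plots", {
  set.seed(9)
  mk <- function(nm) paired_marker_sample(nm, rnorm(10, 1.08, 0.05),
                                          rnorm(10, 1.08, 0.05), units = "s")
  samples <- list(foot = list(stride_time = mk("stride_time"),
                              step_time = mk("step_time")),
                  lumbar = list(stride_time = mk("stride_time"),
                                step_time = mk("step_time")))
  out <- file.path(tempdir(), "agr_test")
  unlink(out, recursive = TRUE)
  rep1 <- agreement_report(samples, task = "single_task", out_dir = out,
                           plots = TRUE)
  expect_s3_class(rep1, "agreement_report")
  expect_equal(nrow(rep1$results), 4)
  files <- list.files(out)
  expect_true(any(grepl("markers_mae_single_task", files)))
  expect_true(any(grepl("markers_correlation_single_task", files)))
  # one Bland-Altman figure per marker x modality plus the r-vs-MAEP scatter
  expect_equal(sum(grepl("bland_altman", files)), 4)
  expect_equal(sum(grepl("r_vs_maep", files)), 1)
})

test_that("identical inputs flag the undefined correlation instead of failing", {
  s <- paired_marker_sample("x", rep(2, 5), rep(2, 5))
  row <- agreement_result(s)
  expect_equal(row$mae_mean, 0)
  expect_true(is.na(row$r))
})
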