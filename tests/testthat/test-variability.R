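test_that("percent_cv matches hand-computed values and rejects bad input", {
  expect_equal(percent_cv(c(1.1, 1.1, 1.1)), 0)
  # sample SD of (0.9, 1.0, 1.1) is exactly 0.1, mean exactly 1
  expect_equal(percent_cv(c(0.9, 1.0, 1.1)), 10.0)
  expect_error(percent_cv(1.0), "at least 2")
  expect_error(percent_cv(c(-2, 0, -1)), "positive")
})

test_that("percent_cv is scale- and permutation-invariant", {
  set.seed(1)
  x <- rlnorm(50, 0, 0.2)
  for (c_scale in c(0.01, 3, 1e4)) {
    expect_equal(percent_cv(c_scale * x), percent_cv(x))
  }
  expect_equal(percent_cv(sample(x)), percent_cv(x))
  expect_gte(percent_cv(x), 0)
})

test_that("bilateral_cv averages per-leg CVs and retains both", {
  # legs built so CVs are exactly 4% and 6%
  leg_with_cv <- function(cv, leg) {
    # three values (m - d, m, m + d) have CV d / m * sqrt(... ) -- instead
    # use (1 - s, 1, 1 + s): mean 1, sd = s, CV = 100 s
    s <- cv / 100
    data.frame(participant = "P01", group = "young", condition = "treadmill",
               leg = leg, stride_index = 1:3,
               stride_time_s = c(1 - s, 1, 1 + s),
               stride_length_m = c(1 - s, 1, 1 + s))
  }
  left <- leg_with_cv(4, "left")
  right <- leg_with_cv(6, "right")
  res <- bilateral_cv(left, right, "stride_time")
  expect_equal(res$cv_percent, 5.0)
  expect_equal(res$cv_left, 4.0)
  expect_equal(res$cv_right, 6.0)
  expect_equal(res$n_strides, 6L)
  # identical legs: equals the single-leg %CV, in both modes
  res_id <- bilateral_cv(left, left, "stride_time")
  expect_equal(res_id$cv_percent, percent_cv(left$stride_time_s))
  res_pool <- bilateral_cv(left, left, "stride_time", mode = "pooled")
  expect_equal(res_pool$cv_percent, percent_cv(left$stride_time_s))
})

test_that("bilateral_cv rejects mismatched trials", {
  a <- data.frame(participant = "P01", condition = "treadmill",
                  stride_time_s = c(1, 1.1, 1.2), stride_length_m = 1:3)
  b <- a
  b$participant <- "P02"
  expect_error(bilateral_cv(a, b, "stride_time"), "mismatched participant")
  b <- a
  b$condition <- "overground"
  expect_error(bilateral_cv(a, b, "stride_time"), "mismatched condition")
})

test_that("simulated stride series recover the generator's CV target", {
  spec <- cohort_spec(cv_dispersion = 0,
                      cv_stride_time = cell_table(3.0),
                      mean_stride_time = cell_table(1.1))
  ss <- simulate_stride_series("young", "treadmill", 10000, spec, seed = 4)
  expect_equal(percent_cv(ss$stride_time_s), 3.0, tolerance = 0.2 / 3.0)
  left <- ss[ss$leg == "left", ]
  right <- ss[ss$leg == "right", ]
  res <- bilateral_cv(left, right, "stride_time")
  expect_equal(res$cv_percent, 3.0, tolerance = 0.2 / 3.0)
  # zero within-participant noise: %CV is exactly zero
  spec0 <- cohort_spec(cv_stride_time = cell_table(0),
                       cv_stride_length = cell_table(0))
  ss0 <- simulate_stride_series("older", "overground", 50, spec0, seed = 9)
  expect_equal(percent_cv(ss0$stride_time_s), 0)
})
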