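test_that("generators are pure functions of (params, seed)", {
  spec <- cohort_spec()
  a <- simulate_stride_series("young", "treadmill", 100, spec, seed = 5)
  b <- simulate_stride_series("young", "treadmill", 100, spec, seed = 5)
  expect_identical(a, b)
  s1 <- simulate_lumbar_accel(rep(1.1, 20), 0.05, 0.1, seed = 3)
  s2 <- simulate_lumbar_accel(rep(1.1, 20), 0.05, 0.1, seed = 3)
  expect_identical(s1, s2)
  l1 <- reference_system("lorenz", duration = 5, seed = 2)
  l2 <- reference_system("lorenz", duration = 5, seed = 2)
  expect_identical(l1, l2)
  c1 <- simulate_cohort(cohort_spec(n_per_group = 2), seed = 8)
  c2 <- simulate_cohort(cohort_spec(n_per_group = 2), seed = 8)
  expect_identical(c1, c2)
})

test_that("stride generator validates labels and counts", {
  spec <- cohort_spec()
  expect_error(simulate_stride_series("child", "treadmill", 10, spec),
               "unknown group")
  expect_error(simulate_stride_series("young", "uphill", 10, spec),
               "unknown condition")
  expect_error(simulate_stride_series("young", "treadmill", 0, spec),
               "positive")
})

test_that("simulated moments converge to the cohort targets at n^(-1/2) rate", {
  spec <- cohort_spec(cv_dispersion = 0,
                      sd_between = c(stride_time = 0, stride_length = 0,
                                     lde = 0))
  for (n in c(500, 5000)) {
    ss <- simulate_stride_series("older", "visual_cues", n, spec, seed = n)
    target_mean <- spec$mean_stride_time["older", "visual_cues"]
    sd_within <- target_mean * spec$cv_stride_time["older", "visual_cues"] / 100
    expect_lt(abs(mean(ss$stride_time_s) - target_mean),
              4 * sd_within / sqrt(n))
    expect_equal(percent_cv(ss$stride_time_s),
                 spec$cv_stride_time["older", "visual_cues"],
                 tolerance = 4 / sqrt(n) + 0.02)
  }
})

test_that("cohort simulation has the full repeated-measures layout", {
  co <- simulate_cohort(cohort_spec(), seed = 1)
  expect_equal(nrow(co$participants), 50)
  expect_equal(nrow(co$measures), 50 * 3 * 3)
  counts <- table(co$measures$participant, co$measures$condition)
  expect_true(all(counts == 3))  # 3 measures per participant x condition
  expect_equal(sort(unique(co$measures$measure)),
               sort(c("stride_time_cv", "stride_length_cv", "lde")))
  # smallest valid cohort runs end-to-end through the ANOVA layer
  tiny <- simulate_cohort(cohort_spec(n_per_group = 2), seed = 2)
  sub <- tiny$measures[tiny$measures$measure == "lde", ]
  expect_s3_class(mixed_anova(sub), "gait_anova")
})

test_that("lumbar accel simulator keeps exact bookkeeping and ground truth", {
  set.seed(10)
  st <- rnorm(180, 1.1, 0.03)
  sim <- simulate_lumbar_accel(st, amplitude_cv = 0.1, sensor_noise_sd = 0.1,
                               sample_rate = 128, seed = 6)
  n_samp <- pmax(2L, as.integer(round(st * 128)))
  expect_equal(nrow(sim$accel$samples), sum(n_samp))
  expect_equal(length(sim$truth$event_indices), length(st) + 1)
  expect_equal(length(sim$truth$stride_times),
               length(sim$truth$event_indices) - 1)
  expect_true(all(diff(sim$truth$event_indices) > 0))
  # events sit at the phase origin of the base waveform: with no noise the
  # vertical channel is maximal at each event
  clean <- simulate_lumbar_accel(rep(1.0, 10), 0, 0, sample_rate = 100)
  ev <- clean$truth$event_indices[1:10]
  expect_equal(clean$accel$samples[ev, "v"],
               rep(max(clean$accel$samples[, "v"]), 10))
  expect_error(simulate_lumbar_accel(numeric(0)), "empty")
  expect_error(simulate_lumbar_accel(c(1, -1)), "positive")
})

test_that("periodic simulation with no noise is exactly periodic", {
  sim <- simulate_lumbar_accel(rep(1.0, 6), 0, 0, sample_rate = 100)
  x <- sim$accel$samples
  expect_equal(x[1:100, ], x[101:200, ])
  expect_equal(x[1:100, ], x[401:500, ])
})

test_that("reference systems behave as chaotic/periodic controls", {
  expect_error(reference_system("rossler"), "arg")
  sine <- reference_system("sine", duration = 10, sample_rate = 100)
  expect_equal(nrow(sine$samples), 1000)
  # three phase-shifted unit sinusoids sum to ~0 at all times
  expect_lt(max(abs(rowSums(sine$samples))), 1e-10)
  # Benettin tangent-space exponents: chaotic vs non-chaotic
  lam_lorenz <- benettin_lyapunov("lorenz", t_total = 100)
  expect_equal(lam_lorenz, 0.906, tolerance = 0.03)
  lam_osc <- benettin_lyapunov("sho", t_total = 100)
  expect_lt(abs(lam_osc), 1e-6)
})
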