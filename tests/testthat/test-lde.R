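test_that("time normalization is exact on identity and linear-ramp cases", {
  # strides already exactly 100 samples long pass through unchanged
  trial <- make_periodic_trial(10, stride_time = 1.0, fs = 100)
  nb <- time_normalize(trial$accel, trial$events[1:9])
  expect_equal(nrow(nb$samples), 800)
  expect_equal(nb$strides_per_bout, 8L)
  expect_equal(nb$samples, trial$accel$samples[1:800, ],
               ignore_attr = TRUE, tolerance = 1e-12)
  # linear ramp: resampling preserves linearity and endpoints
  n <- 500
  ramp <- accel_series(cbind(1:n, 2 * (1:n), -(1:n)), 128)
  ev <- c(1L, 120L, 260L, 501L)  # three unequal strides, last ends at T
  nb2 <- time_normalize(ramp, ev)
  for (j in 1:3) {
    seg <- nb2$samples[((j - 1) * 100 + 1):(j * 100), 1]
    expect_equal(seg[1], ev[j])                      # start endpoint
    expect_equal(seg[100], ev[j + 1] - 1)            # end endpoint
    expect_equal(diff(seg), rep(diff(seg)[1], 99))   # still linear
  }
  expect_error(time_normalize(ramp, c(1, 700)), "out of range")
  expect_error(time_normalize(ramp, c(10, 5)), "strictly increasing")
})

test_that("delay embedding builds the 9D state space by definition", {
  x <- matrix(0:799, nrow = 800, ncol = 3)  # ramp t = 0..799 per axis
  sp <- delay_embed(x, delay = 25, copies = 3)
  expect_equal(dim(sp$states), c(750, 9))
  expect_equal(unname(sp$states[1, ]), rep(c(0, 25, 50), 3))
  expect_equal(unname(sp$states[750, ]), rep(c(749, 774, 799), 3))
  expect_error(delay_embed(x[1:50, ], delay = 25, copies = 3), "too short")
  # constant signal: downstream divergence flags the degeneracy
  spc <- delay_embed(matrix(1, 400, 3), 25, 3)
  expect_error(divergence_curve(spc, 50, 50), "degenerate")
})

test_that("neighbour search equals the exhaustive oracle", {
  set.seed(99)
  for (theiler in c(0, 10, 50)) {
    states <- matrix(rnorm(300 * 9), 300, 9)
    fast <- gaitdyn:::.nn_theiler_cpp(states, as.integer(theiler))
    expect_equal(fast, nn_oracle(states, theiler))
  }
})

test_that("short-term slope fitting is exact on constructed curves", {
  line <- structure(list(t = 0:100, mean_log_div = -3 + 0.02 * (0:100)),
                    class = "divergence_curve")
  expect_equal(fit_short_term_lde(line, window = 50), 2.0)
  flat <- structure(list(t = 0:100, mean_log_div = rep(-1.5, 101)),
                    class = "divergence_curve")
  expect_equal(fit_short_term_lde(flat, 50), 0)
  # saturating curve (the typical divergence shape): halving the window
  # cannot lower the slope
  sat <- structure(list(t = 0:100, mean_log_div = -2 + log1p(0.1 * (0:100))),
                   class = "divergence_curve")
  expect_gte(fit_short_term_lde(sat, 25), fit_short_term_lde(sat, 50))
  expect_error(divergence_slope(line, 0), "fewer than 2")
})

test_that("noise-free periodic gait has near-zero divergence exponent", {
  trial <- make_periodic_trial(95)
  res <- lde_for_trial(trial$accel, trial$events)
  expect_lte(abs(res$lambda_s), 0.05)
  expect_equal(res$n_bouts, 11L)
  expect_length(res$per_bout, 11)
  # identical bouts: trial estimate equals any single-bout estimate
  expect_equal(res$lambda_s, res$per_bout[1], tolerance = 1e-8)
})

test_that("the exponent is invariant to global signal scaling", {
  set.seed(4)
  st <- rnorm(95, 1.1, 0.03)
  sim <- simulate_lumbar_accel(st, 0.05, 0.05, seed = 5)
  ev <- sim$truth$event_indices[1:90]
  r1 <- lde_for_trial(sim$accel, ev)
  scaled <- accel_series(sim$accel$samples * 7.3, sim$accel$sample_rate)
  r2 <- lde_for_trial(scaled, ev)
  expect_equal(r1$lambda_s, r2$lambda_s, tolerance = 1e-8)
})

test_that("median exponent rises with injected stride-to-stride noise", {
  lde_at <- function(noise, seed) {
    set.seed(seed)
    st <- rnorm(95, 1.1, noise * 1.1)
    sim <- simulate_lumbar_accel(st, amplitude_cv = noise,
                                 sensor_noise_sd = 0.02, seed = seed + 1)
    ev <- detect_strides(sim$accel, 1.1)
    lde_for_trial(sim$accel, ev)$lambda_s
  }
  meds <- sapply(c(0.01, 0.03, 0.06), function(nz) {
    median(sapply(1:5, function(r) lde_at(nz, 7000 + 100 * r)))
  })
  expect_true(all(diff(meds) > 0))
})

test_that("curve-average and per-bout aggregation agree for identical bouts", {
  trial <- make_periodic_trial(95)
  r_curve <- lde_for_trial(trial$accel, trial$events, aggregate = "curve")
  r_bout <- lde_for_trial(trial$accel, trial$events, aggregate = "per_bout")
  expect_equal(r_curve$lambda_s, r_bout$lambda_s, tolerance = 1e-8)
})
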