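#' Time-normalize a bout of strides
#'
#' Linearly resamples each stride of a bout to exactly `samples_per_stride`
#' points and concatenates them, removing stride-duration differences so that
#' normalized time is measured in strides (100 samples = one stride by
#' default). Endpoints of each stride are preserved; a stride that is already
#' exactly `samples_per_stride` samples long passes through unchanged.
#'
#' @param accel an [accel_series()].
#' @param events strictly increasing event indices bounding the bout's
#'   strides (`strides + 1` values; for the default 8-stride bout, 9). The
#'   last event may be one past the final sample.
#' @param samples_per_stride resampled points per stride (default 100).
#' @return An object of class `normalized_bout`: list with `samples`
#'   (`strides * samples_per_stride` x 3 matrix), `strides_per_bout`,
#'   `samples_per_stride`.
#' @export
time_normalize <- function(accel, events, samples_per_stride = 100) {
  stopifnot(inherits(accel, "accel_series"))
  events <- as.integer(events)
  if (length(events) < 2) stop("need at least 2 events (1 stride)")
  if (is.unsorted(events, strictly = TRUE)) {
    stop("`events` must be strictly increasing")
  }
  n_samp <- nrow(accel$samples)
  if (events[1] < 1 || events[length(events)] > n_samp + 1L) {
    stop("events out of range of the signal")
  }
  n_strides <- length(events) - 1L
  pieces <- vector("list", n_strides)
  for (j in seq_len(n_strides)) {
    a <- events[j]
    b <- events[j + 1] - 1L  # last sample belonging to stride j
    if (b - a + 1L < 2L) stop("stride ", j, " spans fewer than 2 samples")
    grid <- seq(a, b, length.out = samples_per_stride)
    pieces[[j]] <- apply(accel$samples[a:b, , drop = FALSE], 2, function(col) {
      approx(a:b, col, xout = grid)$y
    })
  }
  structure(
    list(samples = do.call(rbind, pieces),
         strides_per_bout = n_strides,
         samples_per_stride = as.integer(samples_per_stride)),
    class = "normalized_bout"
  )
}

#' Delay-embed a tri-axial bout into a 9D state space
#'
#' Builds the reconstructed state space from the three acceleration axes and
#' their time-delayed copies: state m is
#' `[v(m), v(m+tau), v(m+2*tau), ap(m), ..., ml(m+2*tau)]`. With the defaults
#' (delay 25 = 1/4 gait cycle, 3 copies per axis) an 800-sample bout yields
#' 750 states in 9 dimensions.
#'
#' @param bout a `normalized_bout` (or plain numeric T x 3 matrix).
#' @param delay embedding delay in samples (default 25).
#' @param copies delayed copies per axis (default 3).
#' @return An object of class `state_space`: list with `states`
#'   (M x `3 * copies` matrix, M = T - (copies - 1) * delay), `delay`,
#'   `copies`.
#' @export
delay_embed <- function(bout, delay = 25, copies = 3) {
  x <- if (inherits(bout, "normalized_bout")) bout$samples else as.matrix(bout)
  n <- nrow(x)
  m <- n - (copies - 1L) * delay
  if (m < 2L) stop("bout too short for delay ", delay, " with ", copies,
                   " copies")
  cols <- vector("list", ncol(x) * copies)
  k <- 0L
  for (axis in seq_len(ncol(x))) {
    for (cc in 0:(copies - 1L)) {
      k <- k + 1L
      cols[[k]] <- x[seq_len(m) + cc * delay, axis]
    }
  }
  structure(
    list(states = do.call(cbind, cols), delay = as.integer(delay),
         copies = as.integer(copies)),
    class = "state_space"
  )
}

#' Mean log divergence curve of nearest state-space neighbours
#'
#' For every state, finds its nearest Euclidean neighbour outside a temporal
#' Theiler window (ties broken by smallest index), then follows each pair
#' forward and averages the log Euclidean distances at each horizon step —
#' the Rosenstein construction whose initial slope estimates the short-term
#' local divergence exponent. Pairs with either trajectory running off the
#' end are dropped from the average at that step.
#'
#' @param space a `state_space` from [delay_embed()].
#' @param theiler temporal exclusion half-width in samples; the default, one
#'   normalized stride (100 samples), is the mean-period rule.
#' @param horizon number of forward steps (default 100 = one stride).
#' @return An object of class `divergence_curve`: list with `t` (0..horizon,
#'   normalized samples) and `mean_log_div` (nats).
#' @export
divergence_curve <- function(space, theiler = 100, horizon = 100) {
  stopifnot(inherits(space, "state_space"))
  x <- space$states
  m <- nrow(x)
  if (m <= theiler + 1L) stop("no admissible neighbour pairs: ", m,
                              " states with Theiler window ", theiler)
  if (max(apply(x, 2, function(col) diff(range(col)))) == 0) {
    stop("degenerate input: all states identical (constant signal)")
  }
  nn <- .nn_theiler_cpp(x, as.integer(theiler))
  if (all(is.na(nn))) stop("no admissible neighbour pairs")
  curve <- .mean_log_div_cpp(x, nn, as.integer(horizon), 1e-12)
  structure(
    list(t = 0:as.integer(horizon), mean_log_div = as.numeric(curve),
         neighbours = nn),
    class = "divergence_curve"
  )
}

#' Slope of the initial divergence segment
#'
#' Ordinary least-squares slope of the mean log divergence over
#' `t in [0, window]`, in nats per (normalized) sample.
#'
#' @param curve a `divergence_curve`.
#' @param window fit window length in samples.
#' @return Slope in nats/sample.
#' @export
divergence_slope <- function(curve, window) {
  stopifnot(inherits(curve, "divergence_curve"))
  keep <- curve$t <= window & is.finite(curve$mean_log_div)
  if (sum(keep) < 2) stop("fit window contains fewer than 2 points")
  tt <- curve$t[keep]
  yy <- curve$mean_log_div[keep]
  sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
}

#' Short-term local divergence exponent from a divergence curve
#'
#' Fits the initial slope over `[0, window]` normalized samples and rescales
#' it to nats per stride. The default window, 0-0.5 stride (50 samples), is
#' the dominant short-term convention in trunk-accelerometry work;
#' `window = 100` gives the 0-1-stride variant.
#'
#' @param curve a `divergence_curve` on stride-normalized time.
#' @param window fit window in normalized samples (default 50).
#' @param samples_per_stride normalized samples per stride (default 100).
#' @return Short-term exponent, nats/stride.
#' @export
fit_short_term_lde <- function(curve, window = 50, samples_per_stride = 100) {
  divergence_slope(curve, window) * samples_per_stride
}

#' Local divergence exponent of one walking trial
#'
#' The full estimator: per bout of the plan, time-normalize the strides,
#' delay-embed, and compute a divergence curve; average the curves pointwise
#' across bouts and fit a single short-term slope (the multi-bout convention;
#' `aggregate = "per_bout"` instead fits each bout and averages the slopes).
#'
#' @param accel an [accel_series()].
#' @param events stride event indices (e.g. from [detect_strides()]).
#' @param plan optional [plan_bouts()] result; built from `events`,
#'   `n_bouts` and `strides_per_bout` when `NULL`.
#' @param n_bouts,strides_per_bout bout structure (defaults 11 x 8).
#' @param samples_per_stride,delay,copies embedding parameters (defaults
#'   100, 25, 3: 9D space with quarter-cycle delay).
#' @param theiler,horizon,fit_window divergence-curve parameters in
#'   normalized samples (defaults 100, 100, 50).
#' @param aggregate `"curve"` (average curves, fit once; default) or
#'   `"per_bout"` (fit per bout, average slopes).
#' @return An object of class `lde_result`: list with `lambda_s`
#'   (nats/stride), `per_bout` slopes, the averaged `curve`, `n_bouts` and a
#'   parameter echo.
#' @export
lde_for_trial <- function(accel, events, plan = NULL, n_bouts = 11,
                          strides_per_bout = 8, samples_per_stride = 100,
                          delay = 25, copies = 3,
                          theiler = samples_per_stride,
                          horizon = samples_per_stride,
                          fit_window = round(samples_per_stride / 2),
                          aggregate = c("curve", "per_bout")) {
  aggregate <- match.arg(aggregate)
  if (is.null(plan)) plan <- plan_bouts(events, n_bouts, strides_per_bout)
  curves <- matrix(NA_real_, nrow = plan$n_bouts, ncol = horizon + 1)
  per_bout <- numeric(plan$n_bouts)
  for (b in seq_len(plan$n_bouts)) {
    nb <- time_normalize(accel, plan$bout_events[[b]], samples_per_stride)
    sp <- delay_embed(nb, delay, copies)
    dc <- divergence_curve(sp, theiler, horizon)
    curves[b, ] <- dc$mean_log_div
    per_bout[b] <- fit_short_term_lde(dc, fit_window, samples_per_stride)
  }
  mean_curve <- structure(
    list(t = 0:horizon, mean_log_div = colMeans(curves)),
    class = "divergence_curve"
  )
  lambda <- if (aggregate == "curve") {
    fit_short_term_lde(mean_curve, fit_window, samples_per_stride)
  } else {
    mean(per_bout)
  }
  structure(
    list(lambda_s = lambda, per_bout = per_bout, curve = mean_curve,
         n_bouts = plan$n_bouts,
         params = list(strides_per_bout = plan$strides_per_bout,
                       samples_per_stride = samples_per_stride, delay = delay,
                       copies = copies, theiler = theiler, horizon = horizon,
                       fit_window = fit_window, aggregate = aggregate)),
    class = "lde_result"
  )
}

#' @export
print.lde_result <- function(x, ...) {
  cat(sprintf("<lde_result> lambda_s = %.4f nats/stride (%d bouts x %d strides)\n",
              x$lambda_s, x$n_bouts, x$params$strides_per_bout))
  invisible(x)
}

#' Mean period of a signal, in samples
#'
#' Reciprocal of the power-weighted mean frequency of the periodogram — the
#' Rosenstein mean-period rule used to pick delay and Theiler windows for
#' physical-time (non-stride-normalized) signals.
#'
#' @param x numeric vector (one channel).
#' @return Mean period in samples.
#' @export
mean_period_samples <- function(x) {
  n <- length(x)
  spec <- Mod(fft(x - mean(x)))^2
  half <- 2:floor(n / 2)
  f <- (half - 1) / n  # cycles per sample
  sum(spec[half]) / sum(f * spec[half])
}

#' Rosenstein Lyapunov estimate for a physical-time signal
#'
#' Convenience wrapper applying the divergence estimator to an un-normalized
#' multichannel signal such as a chaotic reference system: embedding delay
#' and fit window default to a quarter of the signal's mean period (the fit
#' must stay inside the initial exponential-divergence regime, clear of the
#' saturation shoulder), the Theiler window to one mean period. Returns the
#' exponent per second so it can be compared directly with
#' [benettin_lyapunov()].
#'
#' @param accel an [accel_series()] (3 channels, uniform sampling).
#' @param delay,theiler,horizon,fit_window sample counts; mean-period-based
#'   defaults when `NULL`.
#' @param copies delayed copies per channel (default 3, i.e. 9D).
#' @return list with `lambda_per_s` (nats/s), `slope_per_sample`, the
#'   `curve`, and the parameters used.
#' @export
lyapunov_rosenstein <- function(accel, delay = NULL, theiler = NULL,
                                horizon = NULL, fit_window = NULL,
                                copies = 3) {
  stopifnot(inherits(accel, "accel_series"))
  mp <- mean_period_samples(accel$samples[, 1])
  delay <- delay %||% max(1L, as.integer(round(mp / 4)))
  theiler <- theiler %||% as.integer(round(mp))
  horizon <- horizon %||% as.integer(round(1.5 * mp))
  fit_window <- fit_window %||% max(2L, as.integer(round(mp / 4)))
  sp <- delay_embed(accel$samples, delay, copies)
  dc <- divergence_curve(sp, theiler, horizon)
  slope <- divergence_slope(dc, fit_window)
  list(lambda_per_s = slope * accel$sample_rate, slope_per_sample = slope,
       curve = dc,
       params = list(mean_period = mp, delay = delay, theiler = theiler,
                     horizon = horizon, fit_window = fit_window,
                     copies = copies))
}
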