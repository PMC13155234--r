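#' Base lumbar acceleration waveform
#'
#' Fixed low-order harmonic shape of one gait cycle used by the acceleration
#' simulator, evaluated at stride phase `phase` in \[0, 1). Coefficients are
#' documented constants so simulated signals are stable across versions:
#' \describe{
#'   \item{vertical}{`cos(2*pi*phi) + 0.5 cos(4*pi*phi) + 0.15 cos(6*pi*phi)`
#'     — single dominant peak exactly at the stride origin (phase 0), which is
#'     what the peak-based event detector locks onto.}
#'   \item{anterior-posterior}{`0.8 sin(2*pi*phi) + 0.3 cos(4*pi*phi)`}
#'   \item{mediolateral}{`0.7 sin(2*pi*phi) + 0.2 sin(6*pi*phi)`}
#' }
#'
#' @param phase numeric vector of stride phases in \[0, 1).
#' @return length(phase) x 3 matrix (v, ap, ml), unit amplitude.
#' @export
base_gait_waveform <- function(phase) {
  cbind(
    v = cos(2 * pi * phase) + 0.5 * cos(4 * pi * phase) +
      0.15 * cos(6 * pi * phase),
    ap = 0.8 * sin(2 * pi * phase) + 0.3 * cos(4 * pi * phase),
    ml = 0.7 * sin(2 * pi * phase) + 0.2 * sin(6 * pi * phase)
  )
}

#' Simulate a lumbar acceleration signal with known stride events
#'
#' Each stride is the fixed [base_gait_waveform()] time-warped to that
#' stride's duration, scaled by a per-stride amplitude factor with the
#' requested coefficient of variation, plus additive white sensor noise.
#' Stride-start samples are returned exactly, enabling oracle tests of event
#' detection and of the divergence estimator's response to injected
#' stride-to-stride noise.
#'
#' @param stride_times vector of stride durations in seconds (all > 0).
#' @param amplitude_cv coefficient of variation (fraction) of the per-stride
#'   amplitude factor; 0 gives identical stride amplitudes.
#' @param sensor_noise_sd SD of additive white noise, m/s^2.
#' @param sample_rate sampling frequency in Hz (default 128).
#' @param amplitude overall scale in m/s^2 applied to the unit waveform
#'   (default 2.5, a typical lumbar vertical acceleration magnitude).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `accel` (an [accel_series()]) and `truth`, a
#'   `ground_truth` list holding `event_indices` (stride-start samples plus
#'   the one-past-end boundary, length `n + 1`) and the input `stride_times`.
#' @export
simulate_lumbar_accel <- function(stride_times, amplitude_cv = 0,
                                  sensor_noise_sd = 0, sample_rate = 128,
                                  amplitude = 2.5, seed = NULL) {
  if (length(stride_times) == 0) stop("`stride_times` must not be empty")
  if (any(stride_times <= 0)) stop("all stride times must be positive")
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  with_seed(seed, {
    n_samp <- pmax(2L, as.integer(round(stride_times * sample_rate)))
    n <- length(stride_times)
    factors <- if (amplitude_cv > 0) {
      pmax(0.1, 1 + amplitude_cv * rnorm(n))
    } else {
      rep(1, n)
    }
    pieces <- vector("list", n)
    for (i in seq_len(n)) {
      phase <- (seq_len(n_samp[i]) - 1L) / n_samp[i]
      pieces[[i]] <- amplitude * factors[i] * base_gait_waveform(phase)
    }
    samples <- do.call(rbind, pieces)
    if (sensor_noise_sd > 0) {
      samples <- samples + matrix(rnorm(length(samples), 0, sensor_noise_sd),
                                  nrow = nrow(samples))
    }
    events <- c(1L, 1L + cumsum(n_samp))
    truth <- structure(
      list(event_indices = events, stride_times = stride_times,
           stride_lengths = NULL),
      class = "ground_truth"
    )
    list(accel = accel_series(samples, sample_rate), truth = truth)
  })
}

#' Canonical reference signals for validating the divergence estimator
#'
#' `lorenz` integrates the standard Lorenz equations (sigma = 10, rho = 28,
#' beta = 8/3) with a fixed-step RK4 integrator at `dt` and samples the result
#' at `sample_rate` after discarding a transient, giving a chaotic three-channel
#' signal whose largest Lyapunov exponent is independently computable with
#' [benettin_lyapunov()]. `sine` returns three phase-shifted sinusoids — a
#' strictly periodic, zero-exponent control.
#'
#' @param name `"lorenz"` or `"sine"`.
#' @param params named list of overrides: for lorenz `sigma`, `rho`, `beta`,
#'   `dt` (integrator step, default 0.001 s), `transient` (discard, default
#'   10 s), `init` (length-3 state); for sine `freq` (Hz, default 1) and
#'   `amplitude`.
#' @param duration output length in seconds (default 300).
#' @param sample_rate output rate in Hz (default 100).
#' @param seed integer seed; for lorenz it jitters the initial condition so
#'   different seeds give different stretches of the attractor. Same seed,
#'   identical trajectory.
#' @return An [accel_series()] with 3 channels.
#' @export
reference_system <- function(name = c("lorenz", "sine"), params = list(),
                             duration = 300, sample_rate = 100, seed = NULL) {
  name <- match.arg(name)
  n_out <- as.integer(round(duration * sample_rate))
  if (name == "sine") {
    freq <- params$freq %||% 1
    amp <- params$amplitude %||% 1
    t <- (seq_len(n_out) - 1L) / sample_rate
    x <- cbind(amp * sin(2 * pi * freq * t),
               amp * sin(2 * pi * freq * t + 2 * pi / 3),
               amp * sin(2 * pi * freq * t + 4 * pi / 3))
    return(accel_series(x, sample_rate))
  }
  sigma <- params$sigma %||% 10
  rho <- params$rho %||% 28
  beta <- params$beta %||% (8 / 3)
  dt <- params$dt %||% 0.001
  transient <- params$transient %||% 10
  init <- params$init %||% c(1, 1, 20)
  init <- with_seed(seed, if (is.null(seed)) init else init + rnorm(3, 0, 0.5))
  every <- as.integer(round(1 / (sample_rate * dt)))
  if (every < 1L) stop("`dt` must not exceed the output sampling interval")
  traj <- .trajectory_cpp(0L, as.numeric(init), c(sigma, rho, beta), dt,
                          as.integer(round(transient / dt)), every, n_out)
  accel_series(traj, sample_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Largest Lyapunov exponent by the Benettin tangent-space method
#'
#' Independent oracle for the divergence-based estimator: integrates the
#' system and its linearised tangent dynamics with fixed-step RK4,
#' renormalising the tangent vector every step and averaging the log stretch
#' rates. For the default Lorenz parameters the literature-standard value is
#' about 0.906 nats/s.
#'
#' @param system `"lorenz"` or `"sho"` (a damped-z harmonic oscillator whose
#'   largest exponent is exactly 0, as a non-chaotic control).
#' @param params named list: lorenz `sigma`/`rho`/`beta`; sho `omega`
#'   (rad/s, default `2*pi`).
#' @param dt integrator step (s).
#' @param t_discard transient discarded before averaging (s).
#' @param t_total averaging time (s).
#' @param init length-3 initial state.
#' @return Largest Lyapunov exponent in nats per second.
#' @export
benettin_lyapunov <- function(system = c("lorenz", "sho"), params = list(),
                              dt = 0.001, t_discard = 20, t_total = 500,
                              init = NULL) {
  system <- match.arg(system)
  if (system == "lorenz") {
    p <- c(params$sigma %||% 10, params$rho %||% 28, params$beta %||% (8 / 3))
    if (is.null(init)) init <- c(1, 1, 20)
    id <- 0L
  } else {
    p <- c(params$omega %||% (2 * pi), 0, 0)
    if (is.null(init)) init <- c(1, 0, 1)
    id <- 1L
  }
  .benettin_cpp(id, as.numeric(init), p, dt, t_discard, t_total)
}
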