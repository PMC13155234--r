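#' Detect stride events from lumbar acceleration
#'
#' Peak-based stride segmentation on the vertical axis (anterior-posterior
#' available as a fallback): the signal is band-pass filtered around the
#' stride frequency with a zero-phase Butterworth filter, and peaks at least
#' `0.6 * expected_stride_time` apart and above half the filtered signal's SD
#' are taken as stride starts. Vertical lumbar acceleration carries the most
#' reliable once-per-stride periodicity in level walking, hence the default
#' axis.
#'
#' @param accel an [accel_series()].
#' @param expected_stride_time approximate stride duration in seconds; sets
#'   the filter band and the minimum inter-event distance.
#' @param axis `"v"` (default) or `"ap"`.
#' @return Strictly increasing integer sample indices of detected stride
#'   events; empty when the signal holds no periodic activity (not an error).
#' @export
detect_strides <- function(accel, expected_stride_time, axis = c("v", "ap")) {
  stopifnot(inherits(accel, "accel_series"))
  axis <- match.arg(axis)
  if (expected_stride_time <= 0) stop("`expected_stride_time` must be positive")
  fs <- accel$sample_rate
  duration <- nrow(accel$samples) / fs
  if (duration < 2 * expected_stride_time) {
    stop(sprintf(
      "signal too short: %.2f s available, need at least 2 strides (%.2f s)",
      duration, 2 * expected_stride_time
    ))
  }
  sig <- accel$samples[, axis]
  f0 <- 1 / expected_stride_time
  band <- c(0.25 * f0, min(3.5 * f0, 0.45 * fs)) / (fs / 2)
  bw <- signal::butter(2, band, type = "pass")
  filt <- signal::filtfilt(bw, sig)
  if (sd(filt) == 0) return(integer(0))
  pk <- pracma::findpeaks(
    filt,
    minpeakheight = 0.5 * sd(filt),
    minpeakdistance = max(1L, as.integer(round(0.6 * expected_stride_time * fs)))
  )
  if (is.null(pk)) return(integer(0))
  sort(as.integer(pk[, 2]))
}

#' Plan divergence-analysis bouts over detected stride events
#'
#' Assigns non-overlapping consecutive windows of `strides_per_bout` strides,
#' earliest first, the structure over which per-bout divergence curves are
#' computed and then averaged. A bout spans `strides_per_bout + 1` consecutive
#' events (shared boundaries), so `n_bouts` bouts require
#' `n_bouts * strides_per_bout + 1` events.
#'
#' @param events strictly increasing event sample indices.
#' @param n_bouts number of bouts (default 11).
#' @param strides_per_bout strides per bout (default 8).
#' @return An object of class `bout_plan`: list with `n_bouts`,
#'   `strides_per_bout`, and `bout_events`, a list of length-`strides_per_bout
#'   + 1` event-index vectors.
#' @export
plan_bouts <- function(events, n_bouts = 11, strides_per_bout = 8) {
  if (is.unsorted(events, strictly = TRUE)) {
    stop("`events` must be strictly increasing")
  }
  if (n_bouts < 1 || strides_per_bout < 1) {
    stop("`n_bouts` and `strides_per_bout` must be positive")
  }
  required <- n_bouts * strides_per_bout + 1
  if (length(events) < required) {
    stop(sprintf("insufficient strides: need %d events, have %d",
                 required, length(events)))
  }
  bouts <- lapply(seq_len(n_bouts), function(b) {
    idx <- ((b - 1) * strides_per_bout + 1):(b * strides_per_bout + 1)
    as.integer(events[idx])
  })
  structure(
    list(n_bouts = as.integer(n_bouts),
         strides_per_bout = as.integer(strides_per_bout),
         bout_events = bouts),
    class = "bout_plan"
  )
}

#' @export
print.bout_plan <- function(x, ...) {
  cat(sprintf("<bout_plan> %d bouts x %d strides (events %d..%d)\n",
              x$n_bouts, x$strides_per_bout,
              x$bout_events[[1]][1],
              x$bout_events[[x$n_bouts]][x$strides_per_bout + 1]))
  invisible(x)
}
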