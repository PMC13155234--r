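#' Uniformly sampled tri-axial acceleration record
#'
#' Container for a lumbar (or reference-system) acceleration time series.
#' Columns are ordered vertical (`v`), anterior-posterior (`ap`),
#' mediolateral (`ml`); units m/s^2 for gait signals.
#'
#' @param samples numeric matrix, T x 3, one row per sample.
#' @param sample_rate sampling frequency in Hz (default 128, the usual
#'   wearable-IMU rate for gait work).
#' @param start_time time of the first sample in seconds.
#' @return An object of class `accel_series`: a list with elements `samples`,
#'   `sample_rate`, `start_time`.
#' @export
accel_series <- function(samples, sample_rate = 128, start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || ncol(samples) != 3L) {
    stop("`samples` must be a numeric T x 3 matrix (v, ap, ml)")
  }
  if (nrow(samples) < 1L) stop("`samples` must contain at least one row")
  if (anyNA(samples)) stop("`samples` must not contain missing values")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number")
  }
  colnames(samples) <- c("v", "ap", "ml")
  structure(
    list(samples = samples, sample_rate = sample_rate, start_time = start_time),
    class = "accel_series"
  )
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf(
    "<accel_series> %d samples x 3 axes @ %g Hz (%.2f s)\n",
    nrow(x$samples), x$sample_rate, nrow(x$samples) / x$sample_rate
  ))
  invisible(x)
}

#' @export
length.accel_series <- function(x) nrow(x$samples)

# Time stamps of each sample, in seconds.
accel_times <- function(x) {
  x$start_time + (seq_len(nrow(x$samples)) - 1L) / x$sample_rate
}
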