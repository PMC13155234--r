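#' Percent coefficient of variation
#'
#' `%CV = (sample SD / sample mean) * 100`, the standard stride-to-stride gait
#' variability index. Uses the n-1 denominator for the SD.
#'
#' @param values positive numeric vector, length >= 2.
#' @return %CV as a single number.
#' @export
percent_cv <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to compute a %CV")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive for a %CV")
  100 * sd(values) / m
}

#' Bilateral stride variability
#'
#' Combines left- and right-leg stride series from the same trial into a
#' single %CV. The default (`mode = "legmean"`) computes the %CV per leg and
#' averages the two; `mode = "pooled"` averages the per-leg SDs and means
#' first and forms one %CV from those (`mean(SDs) / mean(means) * 100`). The
#' two orders differ slightly; both are exposed because bilateral averaging
#' conventions vary between labs.
#'
#' @param left,right `stride_series` data frames (see
#'   [simulate_stride_series()]) for the two legs of one participant and
#'   condition.
#' @param measure `"stride_time"` or `"stride_length"`.
#' @param mode `"legmean"` (default) or `"pooled"`.
#' @return One-row data frame: `participant`, `condition`, `measure`,
#'   `cv_percent`, `n_strides`, `cv_left`, `cv_right`.
#' @export
bilateral_cv <- function(left, right,
                         measure = c("stride_time", "stride_length"),
                         mode = c("legmean", "pooled")) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  for (nm in c("participant", "condition")) {
    if (nm %in% names(left) && nm %in% names(right)) {
      if (!identical(unique(left[[nm]]), unique(right[[nm]]))) {
        stop("mismatched ", nm, " between legs")
      }
    }
  }
  col <- if (measure == "stride_time") "stride_time_s" else "stride_length_m"
  lv <- left[[col]]
  rv <- right[[col]]
  if (is.null(lv) || is.null(rv)) stop("column `", col, "` not found")
  cvl <- percent_cv(lv)
  cvr <- percent_cv(rv)
  cv <- if (mode == "legmean") {
    (cvl + cvr) / 2
  } else {
    100 * mean(c(sd(lv), sd(rv))) / mean(c(mean(lv), mean(rv)))
  }
  data.frame(
    participant = if ("participant" %in% names(left)) left$participant[1] else NA,
    condition = if ("condition" %in% names(left)) left$condition[1] else NA,
    measure = measure,
    cv_percent = cv,
    n_strides = length(lv) + length(rv),
    cv_left = cvl,
    cv_right = cvr,
    stringsAsFactors = FALSE
  )
}
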