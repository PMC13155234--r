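#' Specification of a visually cued treadmill trial
#'
#' Parameters of the projected stepping-target stimulus: targets move
#' backward at belt speed, are spaced by the participant's habitual step
#' length and width, and are scaled to the participant's foot size.
#' Coordinates: walking axis positive forward, origin at the treadmill front
#' edge; cues translate backward (negative velocity) at belt speed.
#'
#' @param belt_speed treadmill belt speed, m/s.
#' @param step_length habitual step length, m (contralateral spacing; half a
#'   stride).
#' @param step_width habitual step width, m.
#' @param foot_length,foot_width participant foot dimensions, m.
#' @param duration trial duration, s; must cover at least one step period.
#' @return An object of class `cue_spec`.
#' @export
cue_spec <- function(belt_speed, step_length, step_width,
                     foot_length = 0.27, foot_width = 0.10, duration = 180) {
  vals <- c(belt_speed = belt_speed, step_length = step_length,
            step_width = step_width, foot_length = foot_length,
            foot_width = foot_width, duration = duration)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad)) stop("all cue parameters must be positive: ",
                        paste(bad, collapse = ", "))
  if (duration < step_length / belt_speed) {
    stop("`duration` must cover at least one step period")
  }
  structure(as.list(vals), class = "cue_spec")
}

#' Generate a visually cued stepping-target sequence
#'
#' Deterministic schedule of foot-sized rectangles: one cue per step, sides
#' strictly alternating, lateral offsets at plus/minus half the step width,
#' all cues sharing velocity `-belt_speed` along the walking axis. The cue
#' arrival period is `step_length / belt_speed`, so consecutive cues land one
#' step length apart and same-side cues exactly two step lengths (one
#' stride) apart.
#'
#' @param spec a [cue_spec()].
#' @param margin fractional margin added to the foot dimensions when sizing
#'   the rectangle (default 0.2, i.e. 20%).
#' @param first_side side of the first cue, `"L"` or `"R"`.
#' @return An object of class `cue_sequence`: data frame with one row per
#'   cue — `side`, `x_spawn` (m, at the front edge), `y_offset` (m),
#'   `t_spawn` (s), `width`, `height` (m), `velocity` (m/s, negative =
#'   backward). The spec is attached as attribute `"spec"`.
#' @export
generate_cue_sequence <- function(spec, margin = 0.2, first_side = c("R", "L")) {
  stopifnot(inherits(spec, "cue_spec"))
  first_side <- match.arg(first_side)
  period <- spec$step_length / spec$belt_speed
  n <- floor(spec$duration / period)
  sides <- rep_len(if (first_side == "R") c("R", "L") else c("L", "R"), n)
  out <- data.frame(
    side = sides,
    x_spawn = 0,
    y_offset = ifelse(sides == "R", -1, 1) * spec$step_width / 2,
    t_spawn = (seq_len(n) - 1) * period,
    width = spec$foot_length * (1 + margin),
    height = spec$foot_width * (1 + margin),
    velocity = -spec$belt_speed,
    stringsAsFactors = FALSE
  )
  attr(out, "spec") <- spec
  attr(out, "period") <- period
  class(out) <- c("cue_sequence", "data.frame")
  out
}

#' Validate a cue sequence against its specification
#'
#' Checks side alternation (against the pattern implied by the first cue),
#' longitudinal spacing (consecutive arrival positions one step length
#' apart, via spawn-time gaps times belt speed), speed match within a
#' relative tolerance, and that lateral offsets take exactly two values
#' symmetric about the midline.
#'
#' @param seq a `cue_sequence`.
#' @param spec the [cue_spec()] to validate against.
#' @param speed_tol relative speed tolerance (default 0.001, i.e. 0.1%).
#' @param spacing_tol absolute spacing tolerance in metres.
#' @return list with `n_violations`, per-check counts, and a `violations`
#'   data frame (`check`, `index`, `detail`).
#' @export
validate_cue_sequence <- function(seq, spec, speed_tol = 0.001,
                                  spacing_tol = 1e-9) {
  viol <- list()
  note <- function(check, index, detail) {
    viol[[length(viol) + 1]] <<- data.frame(
      check = check, index = index, detail = detail, stringsAsFactors = FALSE
    )
  }
  n <- nrow(seq)
  expected_sides <- rep_len(
    if (seq$side[1] == "R") c("R", "L") else c("L", "R"), n
  )
  for (i in which(seq$side != expected_sides)) {
    note("alternation", i, sprintf("side %s, expected %s",
                                   seq$side[i], expected_sides[i]))
  }
  if (n > 1) {
    gaps <- diff(seq$t_spawn) * spec$belt_speed
    for (i in which(abs(gaps - spec$step_length) > spacing_tol)) {
      note("spacing", i + 1,
           sprintf("arrival gap %.6f m, expected %.6f m",
                   gaps[i], spec$step_length))
    }
  }
  for (i in which(abs(seq$velocity + spec$belt_speed) >
                  speed_tol * spec$belt_speed)) {
    note("speed", i, sprintf("velocity %.6f, expected %.6f",
                             seq$velocity[i], -spec$belt_speed))
  }
  offs <- sort(unique(seq$y_offset))
  if (length(offs) != 2 || abs(sum(offs)) > spacing_tol) {
    note("lateral_offsets", NA,
         "offsets must take two values symmetric about the midline")
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(check = character(), index = integer(), detail = character())
  counts <- table(factor(violations$check,
                         levels = c("alternation", "spacing", "speed",
                                    "lateral_offsets")))
  list(n_violations = nrow(violations),
       counts = as.list(counts),
       violations = violations)
}
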