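#' Cohort design for the synthetic gait generator
#'
#' Describes a two-group (young / older), three-condition (overground,
#' treadmill, visually cued treadmill) repeated-measures gait study and the
#' distributions the synthetic generator draws from. Per (group, condition)
#' cell the spec carries mean stride time (s), mean stride length (m), a target
#' stride-to-stride variability expressed as %CV, and a mean local divergence
#' exponent (nats/stride).
#'
#' The default cell values are chosen to emulate the qualitative structure
#' reported for this paradigm: variability and instability highest under
#' visual cues for both groups, older adults above young adults on the
#' treadmill conditions, and near-identical group variability overground.
#' They are plausible laboratory magnitudes, not estimates of any published
#' figure.
#'
#' @param n_per_group participants per group (default 25).
#' @param groups,conditions factor labels; exactly 2 groups and 3 conditions.
#' @param mean_stride_time,mean_stride_length,mean_lde group x condition
#'   matrices of cell means (s, m, nats/stride).
#' @param cv_stride_time,cv_stride_length group x condition matrices of target
#'   within-participant stride-to-stride %CV; the within-participant SD of a
#'   cell is `mean * cv / 100`.
#' @param sd_between named numeric vector of between-participant SDs of the
#'   participant-level means, one per measure (`stride_time` s,
#'   `stride_length` m, `lde` nats/stride).
#' @param sd_within_lde per-condition residual SD of the participant's LDE
#'   value around its participant + cell mean.
#' @param cv_dispersion lognormal sigma of the mean-one participant factor
#'   multiplying the within-participant SDs (participants differ in how
#'   variable they are; the factor is shared across conditions, giving the
#'   repeated-measures correlation of the CV outcomes).
#' @param ar1 lag-1 autocorrelation of successive stride parameters within a
#'   leg; 0 (the default) gives i.i.d. Gaussian strides.
#' @param duration_s condition duration in seconds (default 180, i.e. 3 min);
#'   sets how many strides each simulated trial contains.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [simulate_stride_series()]
#' @export
cohort_spec <- function(n_per_group = 25,
                        groups = c("young", "older"),
                        conditions = c("overground", "treadmill", "visual_cues"),
                        mean_stride_time = cell_table(c(1.06, 1.05, 1.07,
                                                        1.08, 1.06, 1.09),
                                                      groups, conditions),
                        mean_stride_length = cell_table(c(1.46, 1.45, 1.44,
                                                          1.34, 1.32, 1.30),
                                                        groups, conditions),
                        mean_lde = cell_table(c(1.35, 1.10, 1.55,
                                                1.50, 1.45, 1.78),
                                              groups, conditions),
                        cv_stride_time = cell_table(c(1.90, 1.85, 2.90,
                                                      1.90, 2.70, 3.90),
                                                    groups, conditions),
                        cv_stride_length = cell_table(c(2.30, 2.25, 3.30,
                                                        2.30, 3.20, 4.40),
                                                      groups, conditions),
                        sd_between = c(stride_time = 0.06,
                                       stride_length = 0.10,
                                       lde = 0.12),
                        sd_within_lde = 0.08,
                        cv_dispersion = 0.20,
                        ar1 = 0,
                        duration_s = 180) {
  if (length(groups) != 2L) stop("exactly 2 groups are required")
  if (length(conditions) != 3L) stop("exactly 3 conditions are required")
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stop("`n_per_group` must be at least 2")
  }
  spec <- list(
    n_per_group = as.integer(n_per_group),
    groups = as.character(groups),
    conditions = as.character(conditions),
    mean_stride_time = as_cell_table(mean_stride_time, groups, conditions),
    mean_stride_length = as_cell_table(mean_stride_length, groups, conditions),
    mean_lde = as_cell_table(mean_lde, groups, conditions),
    cv_stride_time = as_cell_table(cv_stride_time, groups, conditions),
    cv_stride_length = as_cell_table(cv_stride_length, groups, conditions),
    sd_between = sd_between,
    sd_within_lde = sd_within_lde,
    cv_dispersion = cv_dispersion,
    ar1 = ar1,
    duration_s = duration_s
  )
  for (m in c("mean_stride_time", "mean_stride_length", "mean_lde")) {
    if (any(spec[[m]] <= 0)) stop("all cell means must be positive")
  }
  for (m in c("cv_stride_time", "cv_stride_length")) {
    if (any(spec[[m]] < 0)) stop("within-participant CVs must be non-negative")
  }
  if (any(sd_between < 0) || sd_within_lde < 0 || cv_dispersion < 0) {
    stop("SDs must be non-negative")
  }
  if (abs(ar1) >= 1) stop("`ar1` must lie in (-1, 1)")
  missing_meas <- setdiff(c("stride_time", "stride_length", "lde"),
                          names(sd_between))
  if (length(missing_meas)) {
    stop("`sd_between` must name: ", paste(missing_meas, collapse = ", "))
  }
  structure(spec, class = "cohort_spec")
}

#' Group x condition cell table
#'
#' Small helper building the per-cell matrices used throughout [cohort_spec()]:
#' rows are groups, columns conditions, values filled row-wise (one group's
#' three conditions, then the next group's).
#'
#' @param values numeric vector of length `length(groups) * length(conditions)`
#'   or a single number recycled to every cell.
#' @param groups,conditions dimension labels.
#' @export
cell_table <- function(values, groups = c("young", "older"),
                       conditions = c("overground", "treadmill", "visual_cues")) {
  ng <- length(groups); nc <- length(conditions)
  if (length(values) == 1L) values <- rep(values, ng * nc)
  if (length(values) != ng * nc) {
    stop("`values` must have length ", ng * nc, " (or 1)")
  }
  matrix(values, nrow = ng, ncol = nc, byrow = TRUE,
         dimnames = list(groups, conditions))
}

as_cell_table <- function(x, groups, conditions) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(length(groups), length(conditions)))) {
      stop("cell table must be ", length(groups), " x ", length(conditions))
    }
    dimnames(x) <- list(groups, conditions)
    x
  } else {
    cell_table(x, groups, conditions)
  }
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d per group; groups: %s; conditions: %s\n",
              x$n_per_group, paste(x$groups, collapse = ", "),
              paste(x$conditions, collapse = ", ")))
  cat("mean stride time (s):\n"); print(x$mean_stride_time)
  cat("stride-time %CV targets:\n"); print(x$cv_stride_time)
  cat("mean LDE (nats/stride):\n"); print(x$mean_lde)
  invisible(x)
}

#' Null cohort design
#'
#' A [cohort_spec()] in which every (group, condition) cell shares the same
#' means and variability targets, so that group, condition and interaction
#' effects are all exactly zero. Used for type-I-error simulations.
#'
#' @param n_per_group participants per group.
#' @param ... passed on to [cohort_spec()].
#' @export
null_cohort_spec <- function(n_per_group = 25, ...) {
  cohort_spec(
    n_per_group = n_per_group,
    mean_stride_time = cell_table(1.06),
    mean_stride_length = cell_table(1.40),
    mean_lde = cell_table(1.40),
    cv_stride_time = cell_table(2.2),
    cv_stride_length = cell_table(2.8),
    ...
  )
}

# Draw participant-level random effects for one participant.
draw_participant_effects <- function(spec) {
  list(
    b_time = rnorm(1, 0, spec$sd_between[["stride_time"]]),
    b_len = rnorm(1, 0, spec$sd_between[["stride_length"]]),
    b_lde = rnorm(1, 0, spec$sd_between[["lde"]]),
    # mean-one lognormal factor on within-participant SDs
    cv_factor = exp(rnorm(1, 0, spec$cv_dispersion) - spec$cv_dispersion^2 / 2)
  )
}

# Gaussian or AR(1) stride-parameter draws with stationary SD `sd`.
draw_stride_values <- function(n, mean, sd, ar1 = 0, floor_frac = 0.2) {
  if (sd == 0) {
    x <- rep(mean, n)
  } else if (ar1 == 0) {
    x <- rnorm(n, mean, sd)
  } else {
    e <- rnorm(n, 0, sd * sqrt(1 - ar1^2))
    dev <- as.numeric(stats::filter(e, ar1, method = "recursive"))
    dev[1] <- rnorm(1, 0, sd)
    x <- mean + dev
  }
  pmax(x, floor_frac * mean)  # guard against non-physical negatives
}

#' Simulate a per-trial stride-parameter series
#'
#' Draws one participant's stride times and stride lengths for a single
#' (group, condition) cell: a participant-level mean is drawn once from the
#' between-participant distribution, and strides are then drawn i.i.d. (or
#' AR(1) if the spec requests it) around it with the cell's within-participant
#' SD. Left and right legs are generated as interleaved series.
#'
#' @param group,condition labels present in `spec`.
#' @param n_strides total number of strides across both legs.
#' @param spec a [cohort_spec()].
#' @param seed integer seed; same seed, same output.
#' @param effects optional participant effects (internal use by
#'   [simulate_cohort()]); drawn from the spec when `NULL`.
#' @param participant id label for the output table.
#' @return A `stride_series` data frame with columns `participant`, `group`,
#'   `condition`, `leg`, `stride_index`, `stride_time_s`, `stride_length_m`.
#' @export
simulate_stride_series <- function(group, condition, n_strides, spec,
                                   seed = NULL, effects = NULL,
                                   participant = "P01") {
  if (!group %in% spec$groups) stop("unknown group: ", group)
  if (!condition %in% spec$conditions) stop("unknown condition: ", condition)
  if (!is.numeric(n_strides) || n_strides < 1) {
    stop("`n_strides` must be positive")
  }
  n_strides <- as.integer(n_strides)
  with_seed(seed, {
    if (is.null(effects)) effects <- draw_participant_effects(spec)
    mt <- spec$mean_stride_time[group, condition] + effects$b_time
    ml <- spec$mean_stride_length[group, condition] + effects$b_len
    sd_t <- spec$mean_stride_time[group, condition] *
      spec$cv_stride_time[group, condition] / 100 * effects$cv_factor
    sd_l <- spec$mean_stride_length[group, condition] *
      spec$cv_stride_length[group, condition] / 100 * effects$cv_factor
    times <- draw_stride_values(n_strides, mt, sd_t, spec$ar1)
    lengths <- draw_stride_values(n_strides, ml, sd_l, spec$ar1)
    leg <- rep_len(c("left", "right"), n_strides)
    out <- data.frame(
      participant = participant,
      group = group,
      condition = condition,
      leg = leg,
      stride_index = stats::ave(seq_len(n_strides), leg, FUN = seq_along),
      stride_time_s = times,
      stride_length_m = lengths,
      stringsAsFactors = FALSE
    )
    class(out) <- c("stride_series", "data.frame")
    out
  })
}

#' Simulate a full repeated-measures cohort
#'
#' Generates `2 * n_per_group` participants, each observed in all three
#' conditions. Stride series are simulated per trial; the two %CV outcomes are
#' then computed from those strides with [bilateral_cv()], while the LDE
#' outcome is drawn at the measure level (cell mean + participant intercept +
#' condition residual).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed governing all randomness.
#' @return An object of class `gait_cohort`: list with `spec`, `participants`
#'   (id, group), `strides` (all stride series row-bound), and `measures`, a
#'   long table (participant, group, condition, measure, value) with measures
#'   `stride_time_cv`, `stride_length_cv`, `lde`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(2L * spec$n_per_group))
    grp <- rep(spec$groups, each = spec$n_per_group)
    strides <- vector("list", length(ids) * length(spec$conditions))
    meas <- vector("list", length(strides))
    k <- 0L
    for (i in seq_along(ids)) {
      eff <- draw_participant_effects(spec)
      for (cond in spec$conditions) {
        k <- k + 1L
        mt <- spec$mean_stride_time[grp[i], cond] + eff$b_time
        n_per_leg <- max(2L, as.integer(floor(spec$duration_s / mt)))
        ss <- simulate_stride_series(grp[i], cond, 2L * n_per_leg, spec,
                                     seed = NULL, effects = eff,
                                     participant = ids[i])
        strides[[k]] <- ss
        cv_t <- bilateral_cv(ss[ss$leg == "left", ], ss[ss$leg == "right", ],
                             measure = "stride_time")$cv_percent
        cv_l <- bilateral_cv(ss[ss$leg == "left", ], ss[ss$leg == "right", ],
                             measure = "stride_length")$cv_percent
        lde_val <- spec$mean_lde[grp[i], cond] + eff$b_lde +
          rnorm(1, 0, spec$sd_within_lde)
        meas[[k]] <- data.frame(
          participant = ids[i], group = grp[i], condition = cond,
          measure = c("stride_time_cv", "stride_length_cv", "lde"),
          value = c(cv_t, cv_l, lde_val),
          stringsAsFactors = FALSE
        )
      }
    }
    structure(
      list(
        spec = spec,
        participants = data.frame(participant = ids, group = grp,
                                  stringsAsFactors = FALSE),
        strides = do.call(rbind, strides),
        measures = do.call(rbind, meas)
      ),
      class = "gait_cohort"
    )
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d participants x %d conditions; %d strides\n",
              nrow(x$participants), length(x$spec$conditions),
              nrow(x$strides)))
  invisible(x)
}
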