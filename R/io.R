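#' Write / read an acceleration series as CSV
#'
#' Plain-text interchange format: a `# sample_rate: <Hz>` comment line, then
#' columns `t, a_v, a_ap, a_ml`. Reading verifies uniform sampling (maximum
#' timestamp jitter 1e-6 s) and round-trips losslessly within float printing
#' precision.
#'
#' @param x an [accel_series()].
#' @param path file path.
#' @return `write_accel_csv` returns `path` invisibly; `read_accel_csv`
#'   returns an [accel_series()].
#' @export
write_accel_csv <- function(x, path) {
  stopifnot(inherits(x, "accel_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate: %.10g", x$sample_rate), con)
  df <- data.frame(t = accel_times(x), a_v = x$samples[, 1],
                   a_ap = x$samples[, 2], a_ml = x$samples[, 3])
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path) {
  lines <- readLines(path, n = 1)
  if (length(lines) == 0) stop("empty input file: ", path)
  if (!grepl("^#\\s*sample_rate:", lines[1])) {
    stop("missing `# sample_rate:` header in ", path)
  }
  fs <- as.numeric(sub("^#\\s*sample_rate:\\s*", "", lines[1]))
  df <- read.csv(path, comment.char = "#")
  need <- c("t", "a_v", "a_ap", "a_ml")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty input file: ", path)
  if (nrow(df) > 1) {
    dt <- diff(df$t)
    if (max(abs(dt - 1 / fs)) > 1e-6) {
      stop("non-uniform sampling: timestamp jitter exceeds 1e-6 s")
    }
  }
  accel_series(as.matrix(df[, c("a_v", "a_ap", "a_ml")]),
               sample_rate = fs, start_time = df$t[1])
}

#' Write / read a stride-parameter table as CSV
#'
#' Columns: `participant, group, condition, leg, stride_index,
#' stride_time_s, stride_length_m`.
#'
#' @param strides a `stride_series` data frame (or several row-bound).
#' @param path file path.
#' @export
write_stride_csv <- function(strides, path) {
  need <- c("participant", "group", "condition", "leg", "stride_index",
            "stride_time_s", "stride_length_m")
  missing_cols <- setdiff(need, names(strides))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  write.csv(strides[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stride_csv
#' @export
read_stride_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "group", "condition", "leg", "stride_index",
            "stride_time_s", "stride_length_m")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$stride_time_s <= 0)) stop("stride times must be positive")
  class(df) <- c("stride_series", "data.frame")
  df
}

#' Write / read stride events as JSON
#'
#' @param events integer sample indices.
#' @param path file path.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(list(event_indices = as.integer(events)), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) {
  as.integer(jsonlite::read_json(path, simplifyVector = TRUE)$event_indices)
}

#' Write ground truth (events + stride parameters) as JSON
#'
#' @param truth a `ground_truth` object from [simulate_lumbar_accel()].
#' @param path file path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(event_indices = as.integer(truth$event_indices),
         stride_times = truth$stride_times,
         stride_lengths = truth$stride_lengths),
    path, digits = NA, null = "null"
  )
  invisible(path)
}

#' Write / read a cohort specification as YAML
#'
#' @param spec a [cohort_spec()].
#' @param path file path.
#' @export
write_cohort_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- unclass(spec)
  for (nm in names(obj)) if (is.matrix(obj[[nm]])) {
    obj[[nm]] <- as.numeric(t(obj[[nm]]))  # row-wise, cell_table() order
  }
  obj$sd_between <- as.list(obj$sd_between)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cohort_yaml
#' @export
read_cohort_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(cohort_spec, c(
    list(n_per_group = obj$n_per_group, groups = obj$groups,
         conditions = obj$conditions),
    lapply(obj[c("mean_stride_time", "mean_stride_length", "mean_lde",
                 "cv_stride_time", "cv_stride_length")], function(v) {
      cell_table(as.numeric(v), obj$groups, obj$conditions)
    }),
    list(sd_between = unlist(obj$sd_between),
         sd_within_lde = obj$sd_within_lde,
         cv_dispersion = obj$cv_dispersion, ar1 = obj$ar1,
         duration_s = obj$duration_s)
  ))
}

#' Read a per-participant measures table
#'
#' Accepts either the package's long format (`participant, group, condition,
#' measure, value`) or a wide per-participant layout with one column per
#' condition x measure, named `<measure>.<condition>` with measures
#' `stride_time_cv`, `stride_length_cv`, `lde` — the schema used for
#' supplementary per-participant CV/LDE tables. Fails loudly on anything
#' else.
#'
#' @param path CSV file path.
#' @return Long measures data frame.
#' @export
read_measures_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  long_cols <- c("participant", "group", "condition", "measure", "value")
  if (all(long_cols %in% names(df))) {
    return(df[, long_cols])
  }
  if (!all(c("participant", "group") %in% names(df))) {
    stop("measures CSV must contain `participant` and `group` columns")
  }
  meas_cols <- setdiff(names(df), c("participant", "group"))
  parts <- strsplit(meas_cols, ".", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("wide measures CSV columns must be named `<measure>.<condition>`; ",
         "offending: ",
         paste(meas_cols[lengths(parts) != 2], collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_along(meas_cols), function(j) {
    data.frame(participant = df$participant, group = df$group,
               condition = parts[[j]][2], measure = parts[[j]][1],
               value = as.numeric(df[[meas_cols[j]]]),
               stringsAsFactors = FALSE)
  }))
  known <- c("stride_time_cv", "stride_length_cv", "lde")
  unknown <- setdiff(unique(out$measure), known)
  if (length(unknown)) {
    stop("unknown measures in wide CSV: ", paste(unknown, collapse = ", "))
  }
  out
}

#' Write a study report to disk
#'
#' Emits `report.json` (ANOVA tables, post hocs, simple main effects,
#' significance pattern, provenance), `measures.csv`, and one
#' `anova_<measure>.csv` per outcome.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    pattern = report$pattern,
    provenance = report$provenance,
    results = lapply(report$results, function(r) {
      list(anova = r$anova$table,
           mauchly = r$anova$mauchly,
           sphericity_corrected = r$anova$sphericity_corrected,
           posthoc = r$posthoc,
           simple_effects = r$simple_effects,
           condition_means = as.list(r$condition_means))
    })
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  write.csv(report$measures, file.path(dir, "measures.csv"),
            row.names = FALSE)
  for (m in names(report$results)) {
    write.csv(report$results[[m]]$anova$table,
              file.path(dir, paste0("anova_", m, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
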