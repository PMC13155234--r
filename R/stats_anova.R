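#' Two-by-three mixed ANOVA with sphericity handling
#'
#' Classical SS decomposition for one between-subjects factor (group) and one
#' within-subjects factor (condition), subjects nested in group: the design
#' used to compare age groups across walking conditions. Within-subject
#' effects get a Greenhouse-Geisser correction computed from the pooled
#' within-group covariance of the conditions; by default (`gg = "auto"`) the
#' corrected p is reported only when Mauchly's test rejects sphericity at
#' 0.05, mirroring the usual conditional practice.
#'
#' Requires balanced, complete data (equal n per group, every participant in
#' every condition); unbalanced input is an explicit error since classical SS
#' types then no longer coincide.
#'
#' @param data long-format data frame with columns `participant`, `group`,
#'   `condition` and the response named by `dv`.
#' @param dv name of the response column (default `"value"`).
#' @param gg `"auto"` (correct when Mauchly p < 0.05), `"always"`, `"never"`.
#' @param alpha significance level used by the Mauchly gate and downstream
#'   summaries.
#' @return An object of class `gait_anova`: list with `table` (one row per
#'   effect: `effect`, `ss`, `df1`, `df2`, `ms`, `f`, `p_uncorrected`,
#'   `gg_epsilon`, `p_gg`, `p`, `partial_eta_sq`, `size_class`), `mauchly`
#'   (W, statistic, df, p), `sphericity_corrected`, `ss_subject`,
#'   `ss_error_within`, and design counts.
#' @export
mixed_anova <- function(data, dv = "value", gg = c("auto", "always", "never"),
                        alpha = 0.05) {
  gg <- match.arg(gg)
  need <- c("participant", "group", "condition", dv)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- data.frame(
    participant = as.character(data$participant),
    group = as.character(data$group),
    condition = as.character(data$condition),
    value = as.numeric(data[[dv]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(data$value)) stop("missing values in the response")
  conditions <- sort(unique(data$condition))
  k <- length(conditions)
  tab <- table(data$participant, data$condition)
  if (any(tab != 1L)) {
    stop("incomplete cells: every participant needs exactly one value per condition")
  }
  pg <- unique(data[, c("participant", "group")])
  if (anyDuplicated(pg$participant)) {
    stop("participants must belong to exactly one group")
  }
  groups <- sort(unique(pg$group))
  g <- length(groups)
  n_g <- table(factor(pg$group, levels = groups))
  if (length(unique(as.integer(n_g))) != 1L) {
    stop("unbalanced design: groups have ", paste(n_g, collapse = " vs "),
         " participants")
  }
  n <- as.integer(n_g[1])
  if (n < 2) stop("need at least 2 participants per group")
  big_n <- g * n

  ord <- order(pg$participant)
  pg <- pg[ord, ]
  y <- matrix(NA_real_, nrow = big_n, ncol = k,
              dimnames = list(pg$participant, conditions))
  for (r in seq_len(nrow(data))) {
    y[data$participant[r], data$condition[r]] <- data$value[r]
  }
  gvec <- pg$group

  grand <- mean(y)
  subj_means <- rowMeans(y)
  cond_means <- colMeans(y)
  group_means <- tapply(subj_means, gvec, mean)[groups]
  cell_means <- matrix(NA_real_, g, k, dimnames = list(groups, conditions))
  for (gi in groups) cell_means[gi, ] <- colMeans(y[gvec == gi, , drop = FALSE])

  ss_group <- k * n * sum((group_means - grand)^2)
  ss_subj <- k * sum((subj_means - group_means[gvec])^2)
  ss_cond <- big_n * sum((cond_means - grand)^2)
  ss_int <- n * sum(sweep(sweep(cell_means, 1, group_means - grand),
                          2, cond_means)^2)
  ss_within_total <- sum((y - subj_means)^2)
  ss_err <- ss_within_total - ss_cond - ss_int

  df_group <- g - 1L
  df_subj <- big_n - g
  df_cond <- k - 1L
  df_int <- (g - 1L) * (k - 1L)
  df_err <- (big_n - g) * (k - 1L)

  scale_tot <- sum((y - grand)^2)
  if (ss_subj <= 1e-12 * max(scale_tot, 1) ||
      ss_err <= 1e-12 * max(scale_tot, 1)) {
    stop("zero residual variance: F is undefined for (near-)constant data")
  }

  ms <- c(group = ss_group / df_group, condition = ss_cond / df_cond,
          interaction = ss_int / df_int)
  ms_subj <- ss_subj / df_subj
  ms_err <- ss_err / df_err
  f <- c(group = ms[["group"]] / ms_subj,
         condition = ms[["condition"]] / ms_err,
         interaction = ms[["interaction"]] / ms_err)
  df1 <- c(df_group, df_cond, df_int)
  df2 <- c(df_subj, df_err, df_err)
  p_unc <- pf(f, df1, df2, lower.tail = FALSE)

  # Greenhouse-Geisser epsilon + Mauchly from the pooled covariance
  s_pool <- matrix(0, k, k)
  for (gi in groups) {
    yg <- y[gvec == gi, , drop = FALSE]
    s_pool <- s_pool + (nrow(yg) - 1L) * stats::cov(yg)
  }
  s_pool <- s_pool / df_subj
  cmat <- contr.helmert(k)
  cmat <- sweep(cmat, 2, sqrt(colSums(cmat^2)), "/")  # orthonormal contrasts
  m_mat <- t(cmat) %*% s_pool %*% cmat
  ev <- eigen(m_mat, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(ev)^2 / ((k - 1) * sum(ev^2))
  eps <- min(1, max(eps, 1 / (k - 1)))
  w <- if (all(ev > 0)) prod(ev) / (mean(ev))^(k - 1) else 0
  d_cov <- df_subj
  f_m <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * d_cov)
  chi <- if (w > 0) -d_cov * f_m * log(w) else Inf
  df_m <- k * (k - 1) / 2 - 1
  p_m <- pchisq(chi, df_m, lower.tail = FALSE)

  p_gg <- c(NA,
            pf(f[2], eps * df_cond, eps * df_err, lower.tail = FALSE),
            pf(f[3], eps * df_int, eps * df_err, lower.tail = FALSE))
  use_gg <- gg == "always" || (gg == "auto" && p_m < 0.05)
  p_rep <- p_unc
  if (use_gg) p_rep[2:3] <- p_gg[2:3]

  ss_eff <- c(ss_group, ss_cond, ss_int)
  ss_err_eff <- c(ss_subj, ss_err, ss_err)
  pes_ss <- ss_eff / (ss_eff + ss_err_eff)
  pes_f <- f * df1 / (f * df1 + df2)
  stopifnot(all(abs(pes_ss - pes_f) < 1e-12))  # two-route identity

  table <- data.frame(
    effect = c("group", "condition", "interaction"),
    ss = ss_eff, df1 = df1, df2 = df2,
    ms = c(ms[["group"]], ms[["condition"]], ms[["interaction"]]),
    f = as.numeric(f),
    p_uncorrected = as.numeric(p_unc),
    gg_epsilon = c(NA, eps, eps),
    p_gg = p_gg,
    p = as.numeric(p_rep),
    partial_eta_sq = as.numeric(pes_ss),
    size_class = classify_effect_size(pes_ss),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = table,
         mauchly = list(w = w, statistic = chi, df = df_m, p = p_m),
         sphericity_corrected = use_gg,
         ss_subject = ss_subj, ss_error_within = ss_err,
         ss_within_total = ss_within_total,
         n_per_group = n, k_conditions = k, alpha = alpha,
         cell_means = cell_means, condition_means = cond_means),
    class = "gait_anova"
  )
}

#' @export
print.gait_anova <- function(x, ...) {
  cat(sprintf("2 x %d mixed ANOVA (n = %d/group)%s\n", x$k_conditions,
              x$n_per_group,
              if (x$sphericity_corrected) ", Greenhouse-Geisser corrected" else ""))
  tb <- x$table
  tb$ss <- signif(tb$ss, 5)
  tb$ms <- signif(tb$ms, 5)
  tb$f <- round(tb$f, 3)
  for (cc in c("p_uncorrected", "p_gg", "p")) tb[[cc]] <- signif(tb[[cc]], 3)
  tb$gg_epsilon <- round(tb$gg_epsilon, 3)
  tb$partial_eta_sq <- round(tb$partial_eta_sq, 3)
  print(tb, row.names = FALSE)
  cat(sprintf("Mauchly W = %.4f, p = %.4g\n", x$mauchly$w, x$mauchly$p))
  invisible(x)
}

#' Partial eta squared from an F statistic
#'
#' `eta^2_p = F * df1 / (F * df1 + df2)`, algebraically identical to
#' `SS_effect / (SS_effect + SS_error)` and invariant to Greenhouse-Geisser
#' rescaling of both degrees of freedom.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @return Partial eta squared in \[0, 1\].
#' @export
partial_eta_sq <- function(f, df1, df2) {
  if (any(f < 0)) stop("`f` must be non-negative")
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1")
  f * df1 / (f * df1 + df2)
}

#' Classify a partial eta squared effect size
#'
#' Conventional thresholds: below 0.01 negligible, \[0.01, 0.06) small,
#' \[0.06, 0.14) medium, 0.14 and above large.
#'
#' @param eta_sq numeric vector in \[0, 1\].
#' @return Character vector of labels.
#' @export
classify_effect_size <- function(eta_sq) {
  if (any(eta_sq < 0 | eta_sq > 1)) stop("`eta_sq` must lie in [0, 1]")
  cut(eta_sq, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large")) |>
    as.character()
}

#' Holm-Bonferroni step-down adjustment
#'
#' Thin, validated wrapper over `stats::p.adjust(method = "holm")`, mapping
#' the adjusted values back to input positions.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t-test; `d = mean(a - b) / SD(a - b)`. When the paired
#' differences are all identical and zero (a == b), returns t = 0, p = 1,
#' d = 0 rather than erroring on zero variance.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `t`, `df`, `p`, `cohens_d`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(a) - 1L, p = 1, cohens_d = 0,
                  mean_diff = 0))
    }
    stop("paired differences have zero variance but non-zero mean")
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(d) / sd(d), mean_diff = mean(d))
}

#' Holm-adjusted pairwise condition comparisons
#'
#' Paired t-tests on each pair of conditions (values pooled across groups,
#' one family of three comparisons), with Holm adjustment. Set
#' `by_group = TRUE` for group-specific condition contrasts (one Holm family
#' of three per group).
#'
#' @param data long table as for [mixed_anova()].
#' @param dv response column name.
#' @param by_group run the contrasts within each group separately.
#' @param alpha significance level for the `significant` flag.
#' @return data frame with one row per comparison: `group` (or `"all"`),
#'   `condition_a`, `condition_b`, `mean_diff`, `t`, `df`, `p`, `p_holm`,
#'   `cohens_d`, `significant`.
#' @export
condition_posthoc <- function(data, dv = "value", by_group = FALSE,
                              alpha = 0.05) {
  conditions <- sort(unique(as.character(data$condition)))
  pairs <- utils::combn(conditions, 2, simplify = FALSE)
  run_family <- function(sub, label) {
    rows <- lapply(pairs, function(pr) {
      a <- sub[sub$condition == pr[1], ]
      b <- sub[sub$condition == pr[2], ]
      a <- a[order(a$participant), ]
      b <- b[order(b$participant), ]
      stopifnot(identical(a$participant, b$participant))
      res <- paired_t(a[[dv]], b[[dv]])
      data.frame(group = label, condition_a = pr[1], condition_b = pr[2],
                 mean_diff = res$mean_diff, t = res$t, df = res$df,
                 p = res$p, cohens_d = res$cohens_d,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_holm <- holm_adjust(out$p)
    out$significant <- out$p_holm < alpha
    out
  }
  if (!by_group) {
    run_family(data, "all")
  } else {
    do.call(rbind, lapply(sort(unique(data$group)), function(gr) {
      run_family(data[data$group == gr, ], gr)
    }))
  }
}

#' Holm-adjusted simple main effects of group within condition
#'
#' One between-group contrast per condition (pooled-variance two-sample
#' t-test; the design is balanced), Holm-adjusted as a family of three.
#'
#' @param data long table as for [mixed_anova()].
#' @param dv response column name.
#' @param alpha significance level for the `significant` flag.
#' @return data frame: `condition`, `group_a`, `group_b`, `mean_diff`
#'   (a - b), `t`, `df`, `p`, `p_holm`, `significant`.
#' @export
simple_main_effects <- function(data, dv = "value", alpha = 0.05) {
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2) stop("exactly 2 groups are required")
  conditions <- sort(unique(as.character(data$condition)))
  rows <- lapply(conditions, function(cond) {
    sub <- data[data$condition == cond, ]
    a <- sub[[dv]][sub$group == groups[1]]
    b <- sub[[dv]][sub$group == groups[2]]
    tt <- t.test(a, b, var.equal = TRUE)
    data.frame(condition = cond, group_a = groups[1], group_b = groups[2],
               mean_diff = mean(a) - mean(b), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out$significant <- out$p_holm < alpha
  out
}

#' Post hoc power for a repeated-measures effect
#'
#' Noncentral-F power in the G*Power repeated-measures convention: effect
#' size `f^2 = eta^2 / (1 - eta^2)`; for within and interaction effects the
#' noncentrality is inflated by `m / (1 - rho)` measurements, for the
#' between effect by `m / (1 + (m - 1) rho)`.
#'
#' @param eta_sq partial eta squared of the effect, in \[0, 1).
#' @param n_total total sample size across groups.
#' @param n_groups number of groups.
#' @param n_measurements number of repeated measurements.
#' @param corr_rm assumed correlation among repeated measures, in (-1, 1).
#' @param alpha significance level.
#' @param effect which effect the power refers to.
#' @return Power in \[0, 1\].
#' @export
posthoc_power <- function(eta_sq, n_total, n_groups = 2, n_measurements = 3,
                          corr_rm = 0.5, alpha = 0.05,
                          effect = c("interaction", "within", "between")) {
  effect <- match.arg(effect)
  if (eta_sq < 0 || eta_sq >= 1) stop("`eta_sq` must lie in [0, 1)")
  if (corr_rm <= -1 || corr_rm >= 1) stop("`corr_rm` must lie in (-1, 1)")
  if (n_total < 2 * n_groups) stop("`n_total` too small for the design")
  f2 <- eta_sq / (1 - eta_sq)
  m <- n_measurements
  gg <- n_groups
  if (effect == "between") {
    lambda <- f2 * n_total * m / (1 + (m - 1) * corr_rm)
    df1 <- gg - 1
    df2 <- n_total - gg
  } else {
    lambda <- f2 * n_total * m / (1 - corr_rm)
    df1 <- if (effect == "interaction") (gg - 1) * (m - 1) else m - 1
    df2 <- (n_total - gg) * (m - 1)
  }
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}
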