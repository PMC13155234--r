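# Independent oracles, written from definitional formulas and kept separate
# from the package's implementation paths.

# Cell-means mixed-model SS decomposition via explicit loops.
anova_oracle <- function(data) {
  ids <- sort(unique(data$participant))
  conds <- sort(unique(data$condition))
  groups <- sort(unique(data$group))
  y <- sapply(conds, function(cc) {
    sapply(ids, function(id) {
      data$value[data$participant == id & data$condition == cc]
    })
  })
  gvec <- sapply(ids, function(id) data$group[data$participant == id][1])
  k <- length(conds); g <- length(groups); N <- length(ids)
  n <- N / g
  grand <- mean(y)
  ss_group <- 0
  for (gr in groups) {
    ss_group <- ss_group + k * n * (mean(y[gvec == gr, ]) - grand)^2
  }
  ss_subj <- 0
  for (i in seq_len(N)) {
    ss_subj <- ss_subj + k * (mean(y[i, ]) - mean(y[gvec == gvec[i], ]))^2
  }
  ss_cond <- 0
  for (cc in seq_len(k)) ss_cond <- ss_cond + N * (mean(y[, cc]) - grand)^2
  ss_int <- 0
  for (gr in groups) for (cc in seq_len(k)) {
    cell <- mean(y[gvec == gr, cc])
    ss_int <- ss_int + n * (cell - mean(y[gvec == gr, ]) -
                              mean(y[, cc]) + grand)^2
  }
  ss_err <- 0
  for (i in seq_len(N)) for (cc in seq_len(k)) {
    cell <- mean(y[gvec == gvec[i], cc])
    ss_err <- ss_err + (y[i, cc] - mean(y[i, ]) - cell +
                          mean(y[gvec == gvec[i], ]))^2
  }
  f_group <- (ss_group / (g - 1)) / (ss_subj / (N - g))
  f_cond <- (ss_cond / (k - 1)) / (ss_err / ((N - g) * (k - 1)))
  f_int <- (ss_int / ((g - 1) * (k - 1))) / (ss_err / ((N - g) * (k - 1)))
  list(ss = c(group = ss_group, condition = ss_cond, interaction = ss_int,
              subject = ss_subj, error = ss_err),
       f = c(group = f_group, condition = f_cond, interaction = f_int))
}

# Exhaustive O(M^2) nearest-neighbour search with Theiler exclusion,
# smallest-index tie-break, on a plain distance matrix.
nn_oracle <- function(states, theiler) {
  m <- nrow(states)
  dm <- as.matrix(dist(states))
  vapply(seq_len(m), function(i) {
    cand <- which(abs(seq_len(m) - i) > theiler)
    if (!length(cand)) return(NA_integer_)
    cand[which.min(dm[i, cand])]
  }, integer(1))
}

# A small balanced long table with known structure.
make_long_table <- function(n_per_group = 3, seed = 42, group_shift = 0,
                            cond_shift = c(0, 0, 0), inter = 0, sd = 1) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(2 * n_per_group))
  grp <- rep(c("g1", "g2"), each = n_per_group)
  conds <- c("c1", "c2", "c3")
  rows <- list()
  for (i in seq_along(ids)) {
    subj <- rnorm(1)
    for (j in seq_along(conds)) {
      val <- subj + (grp[i] == "g2") * group_shift + cond_shift[j] +
        (grp[i] == "g2") * (j == 3) * inter + rnorm(1, 0, sd)
      rows[[length(rows) + 1]] <- data.frame(
        participant = ids[i], group = grp[i], condition = conds[j],
        value = val, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Deterministic stride-normalized trial for LDE plumbing tests.
make_periodic_trial <- function(n_strides = 95, stride_time = 1.1,
                                fs = 128) {
  sim <- simulate_lumbar_accel(rep(stride_time, n_strides), 0, 0,
                               sample_rate = fs)
  list(accel = sim$accel,
       events = sim$truth$event_indices[seq_len(n_strides)])
}
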