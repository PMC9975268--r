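# shared fixtures and independent oracles

small_config <- function(...) {
  cohort_config(cohort = list(n = 16L, n_male = 8L), ...)
}

# a noise-free configuration: every stochastic component at the measurement
# level is switched off, so expectations are observed exactly
noiseless_config <- function(...) {
  cohort_config(
    cohort = list(n = 12L, n_male = 6L),
    pep = list(within_sd = 0),
    heart_rate = list(meas_noise_rest = 0, meas_noise_load = 0),
    mental = list(hr_question_noise = 0),
    physical = list(slope_het_sd = 0),
    ...
  )
}

# brute-force pairwise artifact scan: flag beat i when any beat strictly
# less than window_s earlier differs by more than jump_pct percent
oracle_hr_flags <- function(t, hr, jump_pct = 30, window_s = 3) {
  n <- length(t)
  flags <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (t[i] - t[j] < window_s &&
          abs(hr[i] - hr[j]) / hr[j] * 100 > jump_pct) flags[i] <- TRUE
    }
  }
  flags
}

# naive k-NN with the same tie rules, written independently (full sort,
# explicit loops)
oracle_knn <- function(train_x, train_y, test_x, k) {
  classes <- levels(train_y)
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- sqrt(rowSums((train_x - matrix(test_x[i, ], nrow(train_x), 2,
                                        byrow = TRUE))^2))
    ord <- order(d)
    kd <- d[ord][k]
    nb <- ord[d[ord] <= kd + 1e-6]
    cnt <- sapply(classes, function(cl) sum(train_y[nb] == cl))
    sums <- sapply(classes, function(cl) sum(d[nb][train_y[nb] == cl]))
    sums[cnt == 0] <- Inf
    best <- classes[cnt == max(cnt)]
    if (length(best) > 1) best <- best[which.min(sums[best])]
    out[i] <- best
  }
  factor(out, levels = classes)
}

# two-pass least-squares slope, independent of lm()
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
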