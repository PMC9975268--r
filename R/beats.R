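# Beat-level synthesis ----------------------------------------------------
#
# Beats are simulated for the window preceding each BP measurement (the
# epoch the device actually averages).  Within-subject PEP variability at
# rest is dominated by a slow vasomotor-band oscillation (period ~8-15 s)
# plus a small white beat-to-beat component; the slow component survives
# 4-beat averaging, which is why the averaged resting series keeps an SD of
# about 4.5 ms.

#' Simulate beat-level records for a subject
#'
#' Generates one beat-level window per row of `schedule` (a measurement table
#' for a single subject, as produced inside [generate_cohort()]).  Each beat
#' carries a Q-wave-referenced PEP, an R-wave-referenced PEP and the Q-R
#' interval, with `pep_q = pep_r + qr_time` exactly.  The Q-R interval is
#' drawn independently of heart rate.
#'
#' @param subject single-row subjects data frame.
#' @param schedule measurement rows for that subject; needs columns `phase`,
#'   `t_s`, `pep_expected`, `hr_expected`.
#' @param window_s seconds of beats to simulate before each measurement
#'   (default 60); must be positive.
#' @param config generator configuration.
#' @param seed optional seed; by default the current RNG stream is used.
#' @return Data frame with columns `subject_id`, `phase`, `t`, `hr`, `pep_q`,
#'   `pep_r`, `qr_time`.
#' @export
simulate_beats <- function(subject, schedule, window_s = 60,
                           config = cohort_config(), seed = NULL) {
  stopifnot(is.data.frame(subject), nrow(subject) == 1L)
  if (!is.numeric(window_s) || window_s <= 0)
    stop("window_s must be positive", call. = FALSE)
  if (!all(c("phase", "t_s", "pep_expected", "hr_expected") %in% names(schedule)))
    stop("schedule lacks required columns", call. = FALSE)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  }
  out <- lapply(seq_len(nrow(schedule)), function(i)
    .simulate_window(subject, schedule[i, ], window_s, config))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.simulate_window <- function(subj, m, window_s, cfg) {
  hr_e <- max(m$hr_expected, 40)
  rr <- 60 / hr_e
  n <- max(floor(window_s / rr), 4L)  # beats stay inside [t_s - window, t_s]
  t <- m$t_s - window_s + cumsum(rep(rr, n))

  # settling transients after the preceding state change: heart rate
  # approaches its new steady value much more slowly than the (inotropic)
  # PEP, so beats recorded during transitions are off the steady-state
  # PEP~HR relation
  hr_tgt <- rep(hr_e, n); pep_tgt <- rep(m$pep_expected, n)
  if (!is.null(m$hr_prev) && is.finite(m$hr_prev)) {
    seg_len <- cfg$protocol$measurement_gap_s + cfg$protocol$measurement_dur_s
    elapsed <- pmax(t - (m$t_s - seg_len), 0)
    hr_tgt <- hr_tgt + (m$hr_prev - hr_e) * exp(-elapsed / cfg$protocol$hr_onset_tau_s)
    pep_tgt <- pep_tgt + (m$pep_prev - m$pep_expected) *
      exp(-elapsed / cfg$protocol$pep_onset_tau_s)
  }

  hr <- hr_tgt + stats::rnorm(n, 0, cfg$heart_rate$beat_noise_sd)
  rate <- cfg$artifacts$beat_hr_jump_rate
  if (rate > 0) {
    jump <- stats::runif(n) < rate
    hr[jump] <- hr[jump] * (1 + cfg$artifacts$beat_hr_jump_frac)
  }

  amp <- cfg$pep$beat_slow_sd * sqrt(2)
  slow <- amp * sin(2 * pi * t / subj$slow_period_s + subj$slow_phase)
  fast <- stats::rnorm(n, 0, cfg$pep$beat_fast_sd)
  # minute-scale autonomic drift: near-constant within a window (it does not
  # inflate the 60-s within-window SD) but decorrelates windows from each
  # other, mirroring the epoch-level noise of the measurement table
  drift <- stats::rnorm(1, 0, cfg$pep$beat_drift_sd)
  pep_q <- pep_tgt + drift + slow + fast

  qr <- pmax(subj$qr_mean + stats::rnorm(n, 0, cfg$qr$beat_jitter_sd), 5)
  pep_r <- pmax(pep_q - qr, 3)
  pep_q <- pep_r + qr  # identity maintained even when clamped

  data.frame(subject_id = subj$subject_id, phase = m$phase,
             t = t, hr = hr, pep_q = pep_q, pep_r = pep_r, qr_time = qr,
             stringsAsFactors = FALSE)
}

#' Simulate a cuff-pressure curve for one measurement
#'
#' Produces an inflation ramp, a short hold above systolic pressure and a
#' steady linear deflation sampled at 10 Hz.  With `disturbed = TRUE` a
#' smooth pressure bump is injected into the deflation segment whose
#' cumulative rise exceeds the 8 mmHg quality threshold.
#'
#' @param subject single-row subjects data frame.
#' @param measurement single measurement row (needs `phase`, `sbp`).
#' @param disturbed inject a deflation disturbance?
#' @param config generator configuration.
#' @param seed optional seed; by default the current RNG stream is used.
#' @return Data frame with columns `subject_id`, `phase`, `t`, `pressure`
#'   and attribute `disturbed`.
#' @export
simulate_cuff_curve <- function(subject, measurement, disturbed = FALSE,
                                config = cohort_config(), seed = NULL) {
  stopifnot(is.data.frame(measurement), nrow(measurement) == 1L)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  }
  fs <- 10
  peak <- max(measurement$sbp + 35, 120)
  t_inf <- seq(0, 8, by = 1 / fs)
  p_inf <- peak * (t_inf / 8)
  t_hold <- seq(8.1, 9, by = 1 / fs)
  p_hold <- rep(peak, length(t_hold))
  dur_def <- (peak - 30) / 3
  t_def <- seq(9 + 1 / fs, 9 + dur_def, by = 1 / fs)
  p_def <- peak - 3 * (t_def - 9)

  if (isTRUE(disturbed)) {
    t0 <- stats::runif(1, 9 + 0.2 * dur_def, 9 + 0.8 * dur_def)
    a <- stats::runif(1, 13, 18)
    p_def <- p_def + a * exp(-((t_def - t0) / 0.8)^2)
  }

  t <- c(t_inf, t_hold, t_def)
  p <- pmax(c(p_inf, p_hold, p_def) + stats::rnorm(length(t), 0, 0.3), 0)
  structure(
    data.frame(subject_id = subject$subject_id, phase = measurement$phase,
               t = t, pressure = p, stringsAsFactors = FALSE),
    disturbed = isTRUE(disturbed)
  )
}
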