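# Quality control ---------------------------------------------------------
#
# Three rules, applied before any statistics:
#   * beat-level heart-rate artifacts: a change of more than 30% relative to
#     any beat less than 3 s earlier invalidates the beat;
#   * cuff curves: a cumulative pressure rise of more than 8 mmHg during
#     deflation invalidates the BP measurement ("more than" is strict - a
#     rise of exactly 8 mmHg passes);
#   * beat-to-beat data are averaged over four heartbeats, as recommended by
#     the impedance-cardiography manufacturer.

#' Flag heart-rate artifacts in a beat series
#'
#' A beat is flagged when its heart rate differs by more than `jump_pct`
#' percent from any beat less than `window_s` seconds earlier (strictest
#' reading: every pair within the window is compared, relative to the
#' earlier beat).
#'
#' @param beats data frame with columns `t` (seconds, ascending) and `hr`;
#'   multi-subject tables are handled per subject via `subject_id`.
#' @param jump_pct percent change threshold (default 30).
#' @param window_s comparison window in seconds (default 3).
#' @return Logical vector, `TRUE` where the beat is an artifact.
#' @examples
#' b <- data.frame(t = c(0, 1, 2), hr = c(70, 70, 95))
#' flag_hr_artifacts(b)
#' @export
flag_hr_artifacts <- function(beats, jump_pct = 30, window_s = 3) {
  stopifnot(is.data.frame(beats), all(c("t", "hr") %in% names(beats)))
  if (jump_pct <= 0 || window_s <= 0)
    stop("jump_pct and window_s must be positive", call. = FALSE)
  if ("subject_id" %in% names(beats) &&
      length(unique(beats$subject_id)) > 1L) {
    flags <- logical(nrow(beats))
    for (id in unique(beats$subject_id)) {
      idx <- which(beats$subject_id == id)
      flags[idx] <- flag_hr_artifacts(beats[idx, c("t", "hr")],
                                      jump_pct, window_s)
    }
    return(flags)
  }
  t <- beats$t; hr <- beats$hr
  if (is.unsorted(t, strictly = FALSE))
    stop("beat timestamps must be non-decreasing", call. = FALSE)
  n <- length(t)
  flags <- logical(n)
  j <- 1L
  for (i in seq_len(n)) {
    while (t[i] - t[j] >= window_s) j <- j + 1L
    if (j < i) {
      ref <- hr[j:(i - 1L)]
      if (any(abs(hr[i] - ref) / ref * 100 > jump_pct)) flags[i] <- TRUE
    }
  }
  flags
}

#' Validate a cuff-pressure curve
#'
#' The deflation segment is taken from the pressure peak to the end of the
#' recording.  The curve is invalid when the maximum cumulative positive
#' excursion during deflation (largest rise from a running minimum) exceeds
#' `rise_mmhg`; a rise of exactly `rise_mmhg` still passes.
#'
#' @param curve data frame with columns `t` and `pressure`.
#' @param rise_mmhg threshold in mmHg (default 8).
#' @return `TRUE` if the curve is usable, `FALSE` otherwise.
#' @export
check_cuff_curve <- function(curve, rise_mmhg = 8) {
  stopifnot(is.data.frame(curve), all(c("t", "pressure") %in% names(curve)))
  if (nrow(curve) == 0L) stop("empty cuff curve", call. = FALSE)
  p <- curve$pressure[order(curve$t)]
  i0 <- which.max(p)
  if (i0 >= length(p)) return(TRUE)
  defl <- p[i0:length(p)]
  rise <- max(defl - cummin(defl))
  rise <= rise_mmhg
}

#' Average beat-to-beat data over a sliding window
#'
#' Right-aligned sliding mean over the last `window` *valid* beats; invalid
#' beats (per the `valid` column, if present) neither receive nor contribute
#' to averages.  The first `window - 1` valid beats of each subject get `NA`
#' (incomplete window), so the output has the same number of rows as the
#' input.
#'
#' @param beats beat data frame; numeric columns `pep_q`, `pep_r`, `hr`
#'   (those present) are averaged into `*_avg` columns.
#' @param window number of beats (default 4); must be >= 1.
#' @return The input data frame with `*_avg` columns appended.
#' @export
average_beats <- function(beats, window = 4) {
  stopifnot(is.data.frame(beats))
  if (!is.numeric(window) || window < 1 || window != round(window))
    stop("window must be a positive integer", call. = FALSE)
  if ("subject_id" %in% names(beats) &&
      length(unique(beats$subject_id)) > 1L) {
    parts <- lapply(unique(beats$subject_id), function(id)
      average_beats(beats[beats$subject_id == id, ], window))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  valid <- if ("valid" %in% names(beats)) beats$valid else rep(TRUE, nrow(beats))
  cols <- intersect(c("pep_q", "pep_r", "hr"), names(beats))
  for (cl in cols) {
    x <- beats[[cl]][valid]
    avg <- rep(NA_real_, length(x))
    if (length(x) >= window) {
      cs <- cumsum(x)
      avg[window:length(x)] <-
        (cs[window:length(x)] -
           c(0, cs)[(window:length(x)) - window + 1L]) / window
    }
    full <- rep(NA_real_, nrow(beats))
    full[valid] <- avg
    beats[[paste0(cl, "_avg")]] <- full
  }
  beats
}

#' Compare Q-wave and R-wave referenced PEP
#'
#' Computes (i) the pooled Pearson correlation between PEP measured from the
#' Q-wave and from the R-wave, (ii) the mean per-subject SD of the Q-R
#' interval, and (iii) the across-subject correlation between the change in
#' Q-R interval and the change in heart rate from rest to physical load
#' (when phase information is available; otherwise the pooled beat-level
#' correlation between `qr_time` and `hr`).
#'
#' @param beats beat data frame with `pep_q`, `pep_r`, `qr_time` and
#'   optionally `subject_id`, `phase`, `hr`.
#' @return A list with elements `pearson_r`, `qr_sd_ms`, `qr_dhr_r`,
#'   `qr_dhr_p` and `n`.
#' @export
compare_q_vs_r <- function(beats) {
  stopifnot(is.data.frame(beats),
            all(c("pep_q", "pep_r", "qr_time") %in% names(beats)))
  if (nrow(beats) < 3L) stop("need at least 3 beats", call. = FALSE)
  r <- stats::cor(beats$pep_q, beats$pep_r)

  if ("subject_id" %in% names(beats)) {
    qr_sd <- mean(tapply(beats$qr_time, beats$subject_id, stats::sd),
                  na.rm = TRUE)
  } else {
    qr_sd <- stats::sd(beats$qr_time)
  }

  qr_dhr <- c(r = NA_real_, p = NA_real_); n_load <- NA_integer_
  if (all(c("subject_id", "phase", "hr") %in% names(beats))) {
    st <- phase_state(beats$phase)
    per <- lapply(split(beats, beats$subject_id), function(b) {
      s <- phase_state(b$phase)
      if (!any(s == "physical") || !any(b$phase == "rest")) return(NULL)
      c(dqr = mean(b$qr_time[s == "physical"]) - mean(b$qr_time[b$phase == "rest"]),
        dhr = mean(b$hr[s == "physical"]) - mean(b$hr[b$phase == "rest"]))
    })
    per <- do.call(rbind, per)
    if (!is.null(per) && nrow(per) >= 3L) {
      ct <- stats::cor.test(per[, "dqr"], per[, "dhr"])
      qr_dhr <- c(r = unname(ct$estimate), p = ct$p.value)
      n_load <- nrow(per)
    }
  } else if ("hr" %in% names(beats)) {
    ct <- stats::cor.test(beats$qr_time, beats$hr)
    qr_dhr <- c(r = unname(ct$estimate), p = ct$p.value)
    n_load <- nrow(beats)
  }

  list(pearson_r = r, qr_sd_ms = qr_sd,
       qr_dhr_r = unname(qr_dhr["r"]), qr_dhr_p = unname(qr_dhr["p"]),
       n = nrow(beats), n_subjects_load = n_load)
}

#' Apply all quality rules to a cohort
#'
#' Beat-level heart-rate artifacts invalidate the affected beats; when a
#' measurement's beat window contains artifacts (epoch mode, the default) or
#' its cuff curve fails [check_cuff_curve()], the measurement is marked
#' invalid.  Counts are conserved: `n_input = n_valid + exclusions`, and each
#' excluded measurement carries exactly one primary reason (heart-rate
#' artifact takes precedence over cuff disturbance).
#'
#' @param cohort a `pep_cohort`.
#' @param hr_jump_pct,hr_window_s,cuff_rise_mmhg,avg_window QC thresholds
#'   (defaults 30, 3, 8, 4).
#' @param epoch_level if `TRUE` (default) a measurement whose beat window
#'   contains an artifact is excluded wholesale; if `FALSE` only the beats
#'   are flagged.
#' @return A list with the updated `cohort` (beats gain a `valid` column and
#'   `*_avg` columns; measurements' `valid` updated) and a `qc_report`.
#' @export
qc_cohort <- function(cohort, hr_jump_pct = 30, hr_window_s = 3,
                      cuff_rise_mmhg = 8, avg_window = 4,
                      epoch_level = TRUE) {
  stopifnot(inherits(cohort, "pep_cohort"))
  meas <- cohort$measurements
  n_input <- nrow(meas)
  reason <- rep(NA_character_, n_input)

  if (!is.null(cohort$beats)) {
    flags <- flag_hr_artifacts(cohort$beats, hr_jump_pct, hr_window_s)
    cohort$beats$valid <- !flags
    cohort$beats <- average_beats(cohort$beats, avg_window)
    if (epoch_level && any(flags)) {
      bad <- unique(cohort$beats[flags, c("subject_id", "phase")])
      hit <- paste(meas$subject_id, meas$phase) %in%
        paste(bad$subject_id, bad$phase)
      reason[hit] <- "hr_artifact"
    }
  }

  if (!is.null(cohort$cuff_curves)) {
    key <- paste(cohort$cuff_curves$subject_id, cohort$cuff_curves$phase)
    for (k in unique(key)) {
      cur <- cohort$cuff_curves[key == k, ]
      if (!check_cuff_curve(cur, cuff_rise_mmhg)) {
        hit <- paste(meas$subject_id, meas$phase) == k
        reason[hit & is.na(reason)] <- "cuff_disturbance"
      }
    }
  }

  meas$valid <- is.na(reason)
  cohort$measurements <- meas

  report <- structure(list(
    n_input = n_input,
    n_excluded_hr_artifact = sum(reason == "hr_artifact", na.rm = TRUE),
    n_excluded_cuff = sum(reason == "cuff_disturbance", na.rm = TRUE),
    n_valid = sum(meas$valid),
    flags = data.frame(subject_id = meas$subject_id, phase = meas$phase,
                       valid = meas$valid, reason = reason,
                       stringsAsFactors = FALSE),
    thresholds = list(hr_jump_pct = hr_jump_pct, hr_window_s = hr_window_s,
                      cuff_rise_mmhg = cuff_rise_mmhg, avg_window = avg_window)
  ), class = "qc_report")

  list(cohort = cohort, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  measurements in: ", x$n_input, "\n", sep = "")
  cat("  excluded (HR artifact): ", x$n_excluded_hr_artifact,
      " | excluded (cuff): ", x$n_excluded_cuff, "\n", sep = "")
  cat("  valid: ", x$n_valid, "\n", sep = "")
  invisible(x)
}
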