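# Synthetic cohort generation --------------------------------------------

# fractional PEP deficit under physical load at load fraction lf (position of
# the current heart rate between rest and the 80%-max stop threshold).
# An onset component ramps in over the first `onset_ramp_lf` of the range
# (PEP drops as soon as treading starts, at near-resting heart rates), and a
# load-proportional component scaled by the subject's slope-heterogeneity
# multiplier carries the load-response relation.  The total is capped so the
# steepest responders keep a physiologically plausible PEP.
.physical_deficit <- function(lf, slope_het, cfg) {
  phy <- cfg$physical
  d <- phy$onset_frac * pmin(1, lf / phy$onset_ramp_lf) +
    phy$slope_frac * slope_het * lf
  pmin(d, phy$max_deficit)
}

.mental_deficit <- function(reactivity, habituation, question) {
  reactivity * habituation^(question - 1)
}

#' Expected PEP for a subject in a given protocol phase
#'
#' Deterministic (noise-free) phase expectation of the pre-ejection period.
#' Mental phases apply the subject's fractional reactivity with geometric
#' per-question habituation; treading phases apply an onset drop plus a
#' load-proportional reduction reaching roughly half the resting value at the
#' heart-rate stop rule; break phases apply the same physical deficit to the
#' decaying residual load fraction, so PEP recovers monotonically.
#'
#' @param subject a single-row data frame from the `subjects` table of a
#'   [generate_cohort()] result.
#' @param phase a phase label (see [phase_levels()]).
#' @param load_fraction for `ergo_*` phases: current heart-rate position
#'   between rest and the stop threshold (0 = rest, 1 = at threshold).  For
#'   break phases pass the decayed residual.  Must lie in `[0, 1.2]`.
#' @param config the generator configuration the subject was drawn under.
#' @return Expected PEP in ms.
#' @examples
#' cohort <- generate_cohort(seed = 1, beats = "none")
#' s <- cohort$subjects[1, ]
#' simulate_phase_pep(s, "rest")
#' simulate_phase_pep(s, "tsst_Q1")
#' simulate_phase_pep(s, "ergo_E5", load_fraction = 1)
#' @export
simulate_phase_pep <- function(subject, phase, load_fraction = 0,
                               config = cohort_config()) {
  stopifnot(is.data.frame(subject), nrow(subject) == 1L)
  if (!phase %in% phase_levels())
    stop("unknown phase label: ", phase, call. = FALSE)
  if (!is.finite(load_fraction) || load_fraction < 0 || load_fraction > 1.2)
    stop("load_fraction must lie in [0, 1.2]", call. = FALSE)
  p <- subject$pep_rest_mean
  if (grepl("^tsst_Q", phase)) {
    q <- as.integer(sub("tsst_Q", "", phase))
    return(p * (1 - .mental_deficit(subject$mental_reactivity,
                                    subject$habituation_rate, q)))
  }
  if (grepl("^ergo_", phase)) {
    return(p * (1 - .physical_deficit(load_fraction, subject$slope_het, config)))
  }
  p
}

# Simulate the full measurement protocol for one subject.  Returns one row
# per BP-measurement epoch with both the noise-free expectations (used for
# beat-window synthesis) and the observed, epoch-noise values.
.simulate_subject_measurements <- function(subj, cfg) {
  pro <- cfg$protocol
  phy <- cfg$physical
  step_s <- pro$measurement_gap_s + pro$measurement_dur_s

  phase <- character(0); t_end <- numeric(0)
  lf <- numeric(0); lf_hr <- numeric(0); watts <- numeric(0)

  add <- function(ph, t, l, lh, w) {
    phase <<- c(phase, ph); t_end <<- c(t_end, t)
    lf <<- c(lf, l); lf_hr <<- c(lf_hr, lh); watts <<- c(watts, w)
  }

  t <- step_s
  add("rest", t, 0, 0, 0)
  for (q in seq_len(pro$n_questions)) {
    t <- t + step_s
    add(paste0("tsst_Q", q), t, 0, 0, 0)
  }
  t <- t + pro$transfer_s

  # first ascent: weight-adapted steps until measured HR exceeds the stop
  # threshold (or the step cap is hit)
  delta_lf <- phy$step_wkg / subj$capacity_wkg
  hr_range <- phy$hr_frac_stop * subj$hr_max - subj$hr_rest
  hr_stop <- phy$hr_frac_stop * subj$hr_max
  k <- 0L
  hr_noise_k <- numeric(0)
  repeat {
    k <- k + 1L
    t <- t + step_s
    lf_k <- k * delta_lf
    eps <- stats::rnorm(1, 0, cfg$heart_rate$meas_noise_load)
    hr_noise_k <- c(hr_noise_k, eps)
    add(paste0("ergo_E", k), t, lf_k, lf_k, k * phy$step_wkg * subj$weight)
    hr_obs_k <- subj$hr_rest + hr_range * lf_k + eps
    if (hr_obs_k > hr_stop || k >= phy$max_steps) break
  }
  lf_stop <- k * delta_lf
  t_stop <- t

  # mid break: residual load fraction decays exponentially
  for (b in 1:3) {
    t <- t + step_s
    dt <- t - t_stop
    add(paste0("ergo_B", b), t,
        lf_stop * exp(-dt / phy$recovery_tau_pep_s),
        lf_stop * exp(-dt / phy$recovery_tau_hr_s), 0)
  }

  # second ascent: second-to-last step once, then the top step twice
  steps2 <- c(max(k - 1L, 1L), k, k)
  for (i in seq_along(steps2)) {
    t <- t + step_s
    j <- steps2[i]
    add(paste0("ergo_E", k + i), t, j * delta_lf, j * delta_lf,
        j * phy$step_wkg * subj$weight)
  }
  t_stop2 <- t
  for (b in 4:6) {
    t <- t + step_s
    dt <- t - t_stop2
    add(paste0("ergo_B", b), t,
        lf_stop * exp(-dt / phy$recovery_tau_pep_s),
        lf_stop * exp(-dt / phy$recovery_tau_hr_s), 0)
  }

  n <- length(phase)
  state <- phase_state(phase)
  q_idx <- ifelse(grepl("^tsst_Q", phase),
                  suppressWarnings(as.integer(sub("tsst_Q", "", phase))), NA)

  pep_exp <- numeric(n)
  hr_exp <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(q_idx[i])) {
      pep_exp[i] <- subj$pep_rest_mean *
        (1 - .mental_deficit(subj$mental_reactivity, subj$habituation_rate, q_idx[i]))
      hr_exp[i] <- subj$hr_rest + subj$hr_gain_mental
    } else if (grepl("^ergo_", phase[i])) {
      pep_exp[i] <- subj$pep_rest_mean *
        (1 - .physical_deficit(lf[i], subj$slope_het, cfg))
      hr_exp[i] <- subj$hr_rest + hr_range * lf_hr[i]
    } else {
      pep_exp[i] <- subj$pep_rest_mean
      hr_exp[i] <- subj$hr_rest
    }
  }

  # observed epoch values: expectation + epoch noise
  hrc <- cfg$heart_rate
  hr_noise <- stats::rnorm(n, 0, ifelse(state %in% c("physical", "recovery") |
                                          grepl("^ergo_", phase),
                                        hrc$meas_noise_load, hrc$meas_noise_rest))
  # reuse the ascent draws that decided termination so the record matches
  hr_noise[match(paste0("ergo_E", seq_len(k)), phase)] <- hr_noise_k
  hr_obs <- hr_exp + hr_noise
  mental_rows <- !is.na(q_idx)
  hr_obs[mental_rows] <- hr_obs[mental_rows] +
    stats::rnorm(sum(mental_rows), 0, cfg$mental$hr_question_noise)
  pep_obs <- pep_exp + stats::rnorm(n, 0, subj$pep_within_sd)
  pep_obs <- pmax(pep_obs, 20)

  sur <- cfg$surrogates
  heather <- sur$heather$intercept + sur$heather$pep_coef * pep_exp +
    stats::rnorm(n, 0, sur$heather$noise_sd)
  lvet <- sur$lvet$intercept + sur$lvet$pep_coef * pep_exp +
    stats::rnorm(n, 0, sur$lvet$noise_sd)
  sbp <- subj$sbp_rest + sur$sbp$delta_coef * (pep_exp - subj$pep_rest_mean) +
    stats::rnorm(n, 0, sur$sbp$noise_sd)
  dbp <- subj$dbp_rest + sur$dbp$delta_frac * (sbp - subj$sbp_rest) +
    stats::rnorm(n, 0, sur$dbp$noise_sd)

  disturbed <- stats::runif(n) < cfg$artifacts$cuff_disturb_rate

  # steady values of the preceding protocol segment, used by the beat
  # synthesiser to model the settling transient after each state change
  pep_prev <- c(subj$pep_rest_mean, pep_exp[-n])
  hr_prev <- c(subj$hr_rest, hr_exp[-n])
  # the ergometer starts from rest again (subjects recover during transfer)
  i_e1 <- match("ergo_E1", phase)
  pep_prev[i_e1] <- subj$pep_rest_mean
  hr_prev[i_e1] <- subj$hr_rest

  data.frame(
    subject_id = subj$subject_id, phase = phase, state = state,
    t_s = t_end, load_watts = watts, load_fraction = lf,
    pep_expected = pep_exp, hr_expected = hr_exp,
    pep_prev = pep_prev, hr_prev = hr_prev,
    pep = pep_obs, hr = hr_obs, sbp = sbp, dbp = dbp,
    lvet = lvet, heather_index = heather,
    valid = TRUE, cuff_disturbed = disturbed,
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded synthetic stress-protocol cohort
#'
#' Draws subject-level parameters, simulates the full measurement protocol
#' (baseline rest, eight TSST questions, a bimodal incremental ergometer
#' profile with breaks) and optionally beat-level windows and cuff-pressure
#' curves.  Identical `(config, seed)` pairs yield identical datasets.
#'
#' @param config a [cohort_config()] object.
#' @param seed integer master seed; all sub-streams (subjects/measurements,
#'   beats, cuff curves) are derived from it deterministically.
#' @param beats `"rest"` (default) simulates the 60-s beat window preceding
#'   the baseline rest measurement only, `"full"` one window per measurement,
#'   `"none"` skips beat synthesis.
#' @param cuff_curves if `TRUE`, simulate a cuff-pressure curve per
#'   measurement (disturbances injected at the configured rate).
#' @return An object of class `pep_cohort`: a list with elements `subjects`,
#'   `measurements`, `beats` (or `NULL`), `cuff_curves` (or `NULL`), `seed`
#'   and `config`.
#' @examples
#' cohort <- generate_cohort(seed = 1, beats = "none")
#' nrow(cohort$subjects)
#' head(cohort$measurements)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            beats = c("rest", "none", "full"),
                            cuff_curves = FALSE) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  beats <- match.arg(beats)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  streams <- .derive_seeds(as.integer(seed), 3L)

  old <- .save_rng()
  on.exit(.restore_rng(old))

  set.seed(streams[1])
  subjects <- .make_subjects(config)
  measurements <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i)
    .simulate_subject_measurements(subjects[i, ], config)))
  rownames(measurements) <- NULL

  beat_df <- NULL
  if (beats != "none") {
    set.seed(streams[2])
    # "rest" mode reproduces the 60-s pre-calibration window; "full" mode
    # covers every inter-measurement segment, i.e. a continuous recording
    win <- if (beats == "full")
      config$protocol$measurement_gap_s + config$protocol$measurement_dur_s
    else config$protocol$beat_window_s
    beat_df <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
      s <- subjects[i, ]
      m <- measurements[measurements$subject_id == s$subject_id, ]
      if (beats == "rest") m <- m[m$phase == "rest", ]
      simulate_beats(s, m, window_s = win, config = config)
    }))
    rownames(beat_df) <- NULL
  }

  cuff_df <- NULL
  if (isTRUE(cuff_curves)) {
    set.seed(streams[3])
    cuff_df <- do.call(rbind, lapply(seq_len(nrow(measurements)), function(i) {
      m <- measurements[i, ]
      s <- subjects[subjects$subject_id == m$subject_id, ]
      simulate_cuff_curve(s, m, disturbed = m$cuff_disturbed, config = config)
    }))
    rownames(cuff_df) <- NULL
  }

  structure(
    list(subjects = subjects, measurements = measurements,
         beats = beat_df, cuff_curves = cuff_df,
         seed = as.integer(seed), config = config),
    class = "pep_cohort"
  )
}

#' @export
print.pep_cohort <- function(x, ...) {
  ns <- nrow(x$subjects)
  cat("<pep_cohort> ", ns, " subjects (",
      sum(x$subjects$sex == "male"), " M / ",
      sum(x$subjects$sex == "female"), " F), seed ", x$seed, "\n", sep = "")
  cat("  measurements: ", nrow(x$measurements),
      " | beats: ", if (is.null(x$beats)) 0L else nrow(x$beats),
      " | cuff curves: ",
      if (is.null(x$cuff_curves)) 0L else length(unique(paste(
        x$cuff_curves$subject_id, x$cuff_curves$phase))), "\n", sep = "")
  st <- table(x$measurements$state)
  cat("  states:", paste(names(st), st, sep = "=", collapse = " "), "\n")
  invisible(x)
}
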