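# Generator configuration ------------------------------------------------
#
# All tunable parameters of the synthetic cohort live in one nested list so a
# run can be reproduced from (config, seed) alone.  Defaults encode the study
# conditions: 71 subjects (34 M / 37 F), resting PEP 104.5 ms, within-subject
# resting SD 4.5 ms, first-question mental reactivity ~15%, physical reduction
# to ~one half of the resting value at the 80%-of-maximum-heart-rate stop
# rule, and surrogate couplings calibrated to the published coefficients of
# determination.

.default_config <- function() {
  list(
    cohort = list(
      n = 71L,        # cohort size
      n_male = 34L    # males; females are n - n_male
    ),
    anthropometrics = list(
      age_male      = c(mean = 21.4, sd = 2.3),
      age_female    = c(mean = 22.3, sd = 3.2),
      age_bounds    = c(18, 35),
      height_male   = c(mean = 183.3, sd = 7.1),
      height_female = c(mean = 167.6, sd = 4.9),
      weight_male   = c(mean = 79.2, sd = 10.1),
      weight_female = c(mean = 59.2, sd = 6.2),
      height_weight_cor = 0.5
    ),
    pep = list(
      rest_mean         = 104.5, # ms, cohort mean resting PEP
      between_sd        = 6.8,   # ms, between-subject residual SD (latent)
      weight_coef       = 0.15,  # ms per kg, weak positive dependence
      sex_offset_female = -3.2,  # ms, direct female offset (total observed
                                 # sex difference also includes the weight path)
      within_sd         = 4.5,   # ms, measurement-epoch noise (4-beat averaged)
      beat_slow_sd      = 5.4,   # ms, slow (vasomotor-band) beat-level component
      beat_fast_sd      = 2.2,   # ms, white beat-to-beat component
      beat_drift_sd     = 8,     # ms, minute-scale autonomic wander between
                                 # beat windows (constant within a window)
      beat_slow_period_s = c(8, 15) # s, per-subject oscillation period range
    ),
    heart_rate = list(
      rest_mean       = 65,     # bpm
      rest_sd         = 8,      # bpm, between-subject
      rest_pep_cor    = -0.25,  # latent correlation of resting HR with resting PEP
      meas_noise_rest = 2,      # bpm, epoch noise at rest
      meas_noise_load = 3,      # bpm, epoch noise under load
      beat_noise_sd   = 1.5     # bpm, beat-to-beat jitter
    ),
    mental = list(
      reactivity_mean   = 0.15,   # fractional PEP reduction at first question
      reactivity_sd     = 0.08,   # between-subject spread of the reduction
      reactivity_bounds = c(0.005, 0.45),
      habituation       = 0.97,   # geometric per-question decay of the effect
      habituation_sd    = 0.01,
      habituation_bounds = c(0.85, 1),
      hr_gain_per_reactivity = 160, # bpm per unit reactivity (shared drive)
      hr_gain_sd        = 8,      # bpm, subject-level HR-response noise
      hr_question_noise = 3       # bpm, per-question noise
    ),
    physical = list(
      onset_frac      = 0.12,  # immediate fractional PEP drop at exercise onset
      onset_ramp_lf   = 0.15,  # load fraction over which the onset drop ramps in
      slope_frac      = 0.335, # additional fractional drop per unit load fraction
      slope_het_sd    = 0.22,  # between-subject multiplier SD on the slope
      slope_het_bounds = c(0.4, 1.6),
      max_deficit     = 0.68,  # cap on the total fractional reduction
      capacity_wkg    = c(mean = 2.2, sd = 0.25), # W/kg at 80% max heart rate
      capacity_bounds = c(1.6, 2.6),
      step_wkg        = 0.4,   # W/kg per ergometer step ("0.4 x body mass")
      hr_frac_stop    = 0.8,   # stop rule: 80% of (220 - age)
      max_steps       = 7L,    # safety cap on the first ascent
      recovery_tau_hr_s  = 60, # s, exponential HR recovery time constant
      recovery_tau_pep_s = 45  # s, exponential PEP recovery time constant
    ),
    surrogates = list(
      heather = list(intercept = 25, pep_coef = -0.14, noise_sd = 1.8),
      lvet    = list(intercept = 185, pep_coef = 1.25, noise_sd = 33),
      sbp     = list(rest_mean = 120, rest_sd = 8, delta_coef = -1.0, noise_sd = 12.5),
      dbp     = list(rest_mean = 72, rest_sd = 6, delta_frac = 0.1, noise_sd = 4)
    ),
    qr = list(
      mean          = 32,  # ms, Q-to-R interval, cohort mean
      between_sd    = 5,   # ms, between-subject
      beat_jitter_sd = 2   # ms, per-beat (keeps per-subject SD < 4 ms)
    ),
    artifacts = list(
      beat_hr_jump_rate = 0,   # per-beat probability of an injected HR jump
      beat_hr_jump_frac = 0.4, # fractional HR jump size when injected
      cuff_disturb_rate = 0    # per-measurement probability of a disturbed cuff curve
    ),
    protocol = list(
      measurement_gap_s = 60,  # s between the end of one epoch and the next start
      measurement_dur_s = 40,  # s cuff inflation-deflation cycle
      transfer_s        = 300, # s transfer from desk to ergometer
      beat_window_s     = 60,  # s of beats simulated before each measurement
      n_questions       = 8L,  # TSST questions
      hr_onset_tau_s    = 55,  # s, chronotropic settling after a state change
      pep_onset_tau_s   = 15   # s, inotropic (PEP) settling - much faster
    )
  )
}

#' Synthetic cohort configuration
#'
#' Build the configuration block that drives [generate_cohort()].  Called with
#' no arguments it returns the default study conditions: a 71-subject cohort
#' (34 male / 37 female) with resting PEP 104.5 ms, a ~15% first-question
#' mental response with mild per-question habituation, a weight-adapted
#' incremental ergometer protocol terminated at 80% of the age-predicted
#' maximum heart rate, and surrogate couplings (Heather index, LVET, SBP)
#' calibrated to the published correlation strengths.
#'
#' Overrides are given as named nested lists and are validated against the
#' default structure; unknown keys are rejected so typos cannot silently
#' change a run.
#'
#' @param ... named blocks of overrides, e.g.
#'   `cohort_config(cohort = list(n = 12L), pep = list(between_sd = 0))`.
#' @return A named list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(cohort = list(n = 10L, n_male = 5L))
#' cfg$cohort$n
#' @export
cohort_config <- function(...) {
  overrides <- list(...)
  cfg <- .default_config()
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("cohort_config() overrides must be named", call. = FALSE)
    cfg <- .merge_config(cfg, overrides, path = "")
  }
  .validate_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

# recursive merge that refuses keys absent from the defaults
.merge_config <- function(base, override, path) {
  for (nm in names(override)) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]], here)
    } else if (!is.list(base[[nm]]) && is.list(override[[nm]])) {
      # named numeric vectors come back from YAML as named lists
      base[[nm]] <- unlist(override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  n <- cfg$cohort$n
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("cohort size must be a positive integer", call. = FALSE)
  nm <- cfg$cohort$n_male
  if (!is.numeric(nm) || length(nm) != 1L || is.na(nm) || nm < 0 || nm > n)
    stop("n_male must lie in [0, n]", call. = FALSE)
  sds <- c(
    cfg$anthropometrics$age_male["sd"], cfg$anthropometrics$age_female["sd"],
    cfg$anthropometrics$height_male["sd"], cfg$anthropometrics$height_female["sd"],
    cfg$anthropometrics$weight_male["sd"], cfg$anthropometrics$weight_female["sd"],
    cfg$pep$between_sd, cfg$pep$within_sd, cfg$pep$beat_slow_sd, cfg$pep$beat_fast_sd,
    cfg$heart_rate$rest_sd, cfg$mental$reactivity_sd, cfg$physical$slope_het_sd,
    cfg$surrogates$heather$noise_sd, cfg$surrogates$lvet$noise_sd,
    cfg$surrogates$sbp$noise_sd, cfg$qr$between_sd, cfg$qr$beat_jitter_sd
  )
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("standard deviations must be non-negative and finite", call. = FALSE)
  if (cfg$mental$reactivity_mean < 0 || cfg$mental$reactivity_mean >= 1)
    stop("mental reactivity mean must lie in [0, 1)", call. = FALSE)
  if (cfg$mental$habituation < 0 || cfg$mental$habituation > 1)
    stop("habituation rate must lie in [0, 1]", call. = FALSE)
  if (abs(cfg$heart_rate$rest_pep_cor) > 1)
    stop("rest_pep_cor must lie in [-1, 1]", call. = FALSE)
  if (cfg$physical$hr_frac_stop <= 0 || cfg$physical$hr_frac_stop > 1)
    stop("hr_frac_stop must lie in (0, 1]", call. = FALSE)
  rate <- cfg$artifacts$beat_hr_jump_rate
  if (rate < 0 || rate > 1 || cfg$artifacts$cuff_disturb_rate < 0 ||
      cfg$artifacts$cuff_disturb_rate > 1)
    stop("artifact rates must be probabilities", call. = FALSE)
  invisible(cfg)
}

#' Read or write a cohort configuration as YAML
#'
#' The round trip is lossless for numeric scalars and vectors; unknown keys in
#' the file are rejected by [cohort_config()] on re-reading.
#'
#' @param path file path.
#' @param config a `cohort_config` object (for writing).
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  # named numeric vectors become YAML maps so their names survive the trip
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(unclass(config)), path)
  invisible(path)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  subjects:", x$cohort$n, sprintf("(%d M / %d F)", x$cohort$n_male,
                                         x$cohort$n - x$cohort$n_male), "\n")
  cat("  resting PEP:", x$pep$rest_mean, "ms (within-subject SD",
      x$pep$within_sd, "ms)\n")
  cat("  mental reactivity:", x$mental$reactivity_mean,
      "| habituation:", x$mental$habituation, "\n")
  cat("  physical reduction at stop rule: ~",
      round(x$physical$onset_frac + x$physical$slope_frac, 3), "\n", sep = "")
  invisible(x)
}

# truncated-normal draws via the inverse-CDF method: consumes exactly n
# uniforms, which keeps sub-stream reproducibility independent of rejection
# luck
.rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
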