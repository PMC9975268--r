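# Stress-response statistics ----------------------------------------------

.valid_meas <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  need <- c("subject_id", "phase", "pep", "hr")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurements lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- measurements
  if ("valid" %in% names(m)) m <- m[m$valid, ]
  if (!"state" %in% names(m)) m$state <- phase_state(m$phase)
  m
}

.rest_reference <- function(m) {
  cols <- intersect(c("pep", "hr", "sbp"), names(m))
  r <- m[m$phase == "rest", c("subject_id", cols)]
  r <- r[!duplicated(r$subject_id), ]
  names(r) <- c("subject_id", paste0(cols, "_rest"))
  r
}

#' Per-phase PEP summaries
#'
#' Mean absolute PEP and mean relative PEP (each measurement divided by the
#' subject's baseline rest value) per protocol phase, with bootstrap 95%
#' confidence intervals (resampling subjects).  Subjects without a baseline
#' rest measurement are dropped with a warning.  `n` declines across
#' ergometer steps as subjects reach their heart-rate stop rule.
#'
#' @param measurements a measurement table (see [generate_cohort()]).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap (default 1).
#' @return Data frame with columns `phase`, `n`, `pep_mean`, `rel_mean`,
#'   `rel_lo`, `rel_hi`.
#' @export
phase_summaries <- function(measurements, n_boot = 1000, seed = 1) {
  m <- .valid_meas(measurements)
  ref <- .rest_reference(m)
  no_ref <- setdiff(unique(m$subject_id), ref$subject_id)
  if (length(no_ref)) {
    warning("excluding ", length(no_ref),
            " subject(s) without a rest reference")
    m <- m[!m$subject_id %in% no_ref, ]
  }
  m <- merge(m, ref[, c("subject_id", "pep_rest")], by = "subject_id")
  m$rel <- m$pep / m$pep_rest

  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  phases <- intersect(phase_levels(), unique(m$phase))
  rows <- lapply(phases, function(ph) {
    d <- m[m$phase == ph, ]
    subj_rel <- tapply(d$rel, d$subject_id, mean)
    boot <- replicate(n_boot, mean(sample(subj_rel, replace = TRUE)))
    data.frame(phase = ph, n = length(subj_rel),
               pep_mean = mean(d$pep), rel_mean = mean(subj_rel),
               rel_lo = unname(stats::quantile(boot, 0.025)),
               rel_hi = unname(stats::quantile(boot, 0.975)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.reg_row <- function(fit, stratum, n) {
  sm <- summary(fit)
  co <- stats::coef(fit)
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  data.frame(stratum = stratum, slope = unname(co[2]),
             intercept = unname(co[1]), r_squared = sm$r.squared,
             p_value = p, n = n, stringsAsFactors = FALSE)
}

#' Pooled correlations of PEP with cardiovascular surrogates
#'
#' Ordinary least-squares fits of PEP against the Heather index, heart rate,
#' LVET, and (as within-subject deltas from rest) systolic blood pressure,
#' pooled across all valid measurements.  The heart-rate relation is
#' additionally fitted with a polynomial to accommodate its curvature.
#'
#' @param measurements measurement table.
#' @param beats optional beat-level table (e.g. from a
#'   `generate_cohort(beats = "full")` run).  When supplied, the PEP/heart-
#'   rate relation is fitted on the 4-beat-averaged beat series - the
#'   densest data available, including the settling transients between load
#'   states - instead of on measurement epochs, matching how a continuous
#'   recording would be pooled.
#' @param poly_degree degree of the supplementary polynomial HR fit
#'   (default 2).
#' @return A list with a data frame `fits` (one row per surrogate:
#'   `heather_index`, `hr`, `lvet`, `sbp_delta`) and scalar
#'   `hr_poly_r_squared`.
#' @export
correlate_surrogates <- function(measurements, beats = NULL, poly_degree = 2) {
  m <- .valid_meas(measurements)
  if (length(unique(m$state[m$state != "recovery"])) < 2L)
    stop("need at least two load strata", call. = FALSE)
  for (v in c("heather_index", "hr", "lvet", "sbp"))
    if (!v %in% names(m)) stop("missing column: ", v, call. = FALSE)

  fits <- list()
  for (v in c("heather_index", "lvet")) {
    .stop_if_constant(m[[v]], v)
    fits[[v]] <- .reg_row(stats::lm(m$pep ~ m[[v]]), v, nrow(m))
  }

  if (is.null(beats)) {
    hr_d <- data.frame(pep = m$pep, hr = m$hr)
  } else {
    b <- beats
    if (!all(c("pep_q_avg", "hr_avg") %in% names(b)))
      b <- average_beats(b, 4)
    ok <- stats::complete.cases(b$pep_q_avg, b$hr_avg)
    hr_d <- data.frame(pep = b$pep_q_avg[ok], hr = b$hr_avg[ok])
  }
  .stop_if_constant(hr_d$hr, "hr")
  fits[["hr"]] <- .reg_row(stats::lm(pep ~ hr, data = hr_d), "hr", nrow(hr_d))

  ref <- .rest_reference(m)
  d <- merge(m, ref, by = "subject_id")
  d$d_pep <- d$pep - d$pep_rest
  d$d_sbp <- d$sbp - d$sbp_rest
  .stop_if_constant(d$d_pep, "d_pep")
  fits[["sbp_delta"]] <- .reg_row(stats::lm(d$d_sbp ~ d$d_pep), "sbp_delta",
                                  nrow(d))

  poly_fit <- stats::lm(pep ~ stats::poly(hr, poly_degree), data = hr_d)
  out <- do.call(rbind, fits[c("heather_index", "hr", "lvet", "sbp_delta")])
  rownames(out) <- NULL
  list(fits = out, hr_poly_r_squared = .r_squared(poly_fit))
}

#' Load-stratified PEP ~ heart-rate regressions
#'
#' One ordinary least-squares regression of PEP on heart rate per load state
#' (rest, mental, physical).  The coupling strengthens with sympathetic
#' activation: nearly flat at rest, moderate under mental stress, tight
#' under treading.
#'
#' @param measurements measurement table.
#' @return Data frame with one row per stratum: `stratum`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
stratified_hr_regression <- function(measurements) {
  m <- .valid_meas(measurements)
  rows <- lapply(c("rest", "mental", "physical"), function(st) {
    d <- m[m$state == st, ]
    if (nrow(d) < 3L)
      stop("stratum '", st, "' has fewer than 3 measurements", call. = FALSE)
    .reg_row(stats::lm(pep ~ hr, data = d), st, nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject PEP/heart-rate regression slopes
#'
#' Fits one least-squares line per subject and summarises the
#' between-subject heterogeneity of the slopes (mean, flattest, steepest).
#'
#' @param measurements measurement table.
#' @param states which load states to include (default all but recovery).
#' @param min_n minimum measurements per subject (default 4).
#' @return A list with `slopes` (data frame: `subject_id`, `slope`,
#'   `intercept`, `n`) and `summary` (mean, sd, flattest, steepest).
#' @export
per_subject_slopes <- function(measurements,
                               states = c("rest", "mental", "physical"),
                               min_n = 4) {
  m <- .valid_meas(measurements)
  m <- m[m$state %in% states, ]
  rows <- lapply(split(m, m$subject_id), function(d) {
    if (nrow(d) < min_n || length(unique(d$hr)) < 2L) return(NULL)
    fit <- stats::lm(pep ~ hr, data = d)
    data.frame(subject_id = d$subject_id[1],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, rows)
  rownames(slopes) <- NULL
  list(slopes = slopes,
       summary = c(mean = mean(slopes$slope), sd = stats::sd(slopes$slope),
                   flattest = max(slopes$slope), steepest = min(slopes$slope)))
}

#' PEP by load state at matched heart rates
#'
#' Averages PEP within heart-rate bins (default width 12 bpm) separately per
#' load state and reports how often the rest > mental > physical ordering
#' holds across bins shared by all three states.  A heart-rate-adjusted
#' state contrast with cluster-robust (by subject) standard errors is
#' reported alongside.
#'
#' @param measurements measurement table.
#' @param hr_bin_width bin width in bpm (default 12); must be positive.
#' @return List with `bins` (per bin x state mean PEP and n), the fraction
#'   `ordering_frac` of fully shared bins with the expected ordering, and
#'   `contrasts` (HR-adjusted state effects with cluster-robust p-values).
#' @export
matched_hr_contrast <- function(measurements, hr_bin_width = 12) {
  if (!is.numeric(hr_bin_width) || hr_bin_width <= 0)
    stop("hr_bin_width must be positive", call. = FALSE)
  m <- .valid_meas(measurements)
  m <- m[m$state %in% c("rest", "mental", "physical"), ]
  m$bin <- floor(m$hr / hr_bin_width) * hr_bin_width

  agg <- stats::aggregate(pep ~ bin + state, data = m, FUN = mean)
  cnt <- stats::aggregate(pep ~ bin + state, data = m, FUN = length)
  names(cnt)[3] <- "n"
  bins <- merge(agg, cnt, by = c("bin", "state"))

  shared <- Reduce(intersect, lapply(split(bins$bin, bins$state), unique))
  ord_ok <- vapply(shared, function(b) {
    v <- bins[bins$bin == b, ]
    v$pep[v$state == "rest"] > v$pep[v$state == "mental"] &&
      v$pep[v$state == "mental"] > v$pep[v$state == "physical"]
  }, logical(1))
  ordering_frac <- if (length(ord_ok)) mean(ord_ok) else NA_real_

  # HR-adjusted contrast, clustered by subject (stand-in for the original
  # mixed-model analysis)
  m$state <- factor(m$state, levels = c("rest", "mental", "physical"))
  fit <- stats::lm(pep ~ hr + state, data = m)
  ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovCL(fit, cluster = m$subject_id))
  rows <- grep("^state", rownames(ct))
  contrasts <- data.frame(term = rownames(ct)[rows],
                          estimate = ct[rows, 1], p_value = ct[rows, 4],
                          stringsAsFactors = FALSE)
  rownames(contrasts) <- NULL

  list(bins = bins, ordering_frac = ordering_frac,
       shared_bins = length(ord_ok), contrasts = contrasts)
}

#' Resting-PEP covariates: sex, weight, height
#'
#' Female-minus-male difference in resting PEP (Welch two-sample test) and
#' the coefficients of determination of resting PEP on body weight and
#' height.
#'
#' @param subjects subjects table.
#' @param measurements measurement table.
#' @return List with `sex_difference_ms`, `sex_p_value`, `r2_weight`,
#'   `p_weight`, `r2_height`, `p_height`.
#' @export
covariates_and_anthropometrics <- function(subjects, measurements) {
  m <- .valid_meas(measurements)
  rest <- m[m$phase == "rest", c("subject_id", "pep")]
  if (nrow(rest) == 0L) stop("no resting measurements", call. = FALSE)
  d <- merge(rest, subjects[, c("subject_id", "sex", "weight", "height")],
             by = "subject_id")

  if (length(unique(d$sex)) < 2L) {
    sex_diff <- NA_real_; sex_p <- NA_real_
  } else {
    tt <- stats::t.test(pep ~ sex, data = d)  # female - male (alphabetical)
    sex_diff <- unname(diff(rev(tt$estimate)))
    sex_p <- tt$p.value
  }
  fw <- summary(stats::lm(pep ~ weight, data = d))
  fh <- summary(stats::lm(pep ~ height, data = d))
  list(sex_difference_ms = sex_diff, sex_p_value = sex_p,
       r2_weight = fw$r.squared, p_weight = fw$coefficients[2, 4],
       r2_height = fh$r.squared, p_height = fh$coefficients[2, 4])
}
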