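# Propagating PEP variability into SBP measurement uncertainty ------------

#' Polynomial fit of PEP on SBP
#'
#' Least-squares polynomial of expected PEP as a function of systolic
#' pressure, with the residual spread summarised both pooled and within SBP
#' bins.  This is the "best guess" a device could make for the pre-ejection
#' period when only pressure is known.
#'
#' @param measurements measurement table (valid rows are used).
#' @param degree polynomial degree (default 2).
#' @param bin_width SBP bin width in mmHg for the binned residual SDs
#'   (default 10).
#' @return Object of class `pep_sbp_fit`: coefficients, SBP support,
#'   pooled residual SD, binned residual SDs.
#' @export
fit_pep_sbp <- function(measurements, degree = 2, bin_width = 10) {
  m <- .valid_meas(measurements)
  if (!"sbp" %in% names(m)) stop("missing column: sbp", call. = FALSE)
  if (length(unique(m$sbp)) < degree + 2)
    stop("need at least degree + 2 distinct SBP values", call. = FALSE)
  fit <- stats::lm(pep ~ stats::poly(sbp, degree, raw = TRUE), data = m)
  res <- stats::residuals(fit)
  support <- range(m$sbp)
  breaks <- seq(floor(support[1] / bin_width) * bin_width,
                ceiling(support[2] / bin_width) * bin_width, by = bin_width)
  bin <- cut(m$sbp, breaks, include.lowest = TRUE)
  bin_sd <- tapply(res, bin, stats::sd)
  bin_n <- tapply(res, bin, length)
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  keep <- !is.na(bin_sd) & bin_n >= 5
  structure(list(
    coefficients = unname(stats::coef(fit)),
    degree = degree, support = support,
    residual_sd = stats::sd(res),
    bins = data.frame(sbp = centers[keep], sd = unname(bin_sd[keep]),
                      n = unname(bin_n[keep])),
    n = nrow(m)
  ), class = "pep_sbp_fit")
}

#' @export
print.pep_sbp_fit <- function(x, ...) {
  cat("<pep_sbp_fit> degree", x$degree, "on", x$n, "measurements\n")
  cat("  support:", paste(round(x$support, 1), collapse = "-"),
      "mmHg | pooled residual SD:", round(x$residual_sd, 2), "ms\n")
  invisible(x)
}

#' Evaluate a PEP-on-SBP fit
#' @param object a `pep_sbp_fit`.
#' @param newdata numeric vector of SBP values (must lie within the fitted
#'   support).
#' @param ... unused.
#' @return Predicted PEP in ms.
#' @export
predict.pep_sbp_fit <- function(object, newdata, ...) {
  s <- newdata
  if (any(s < object$support[1] - 1e-9 | s > object$support[2] + 1e-9))
    stop("SBP outside the fitted support", call. = FALSE)
  co <- object$coefficients
  vapply(s, function(si) sum(co * si^(0:object$degree)), numeric(1))
}

# polynomial evaluation without the support guard, for internal curve
# extension when inverting band edges near the edge of the fitted range
.predict_poly <- function(fit, sbp) {
  co <- fit$coefficients
  vapply(sbp, function(si) sum(co * si^(0:fit$degree)), numeric(1))
}

# dense, strictly decreasing central PTT curve over the widest usable SBP
# range: the model support, truncated to the longest monotone stretch
# overlapping the working interval [lo, hi]
.dense_ptt_curve <- function(model, fit, lo, hi) {
  s <- seq(model$sbp_support[1], model$sbp_support[2], length.out = 4001)
  p <- ptt_at(model, s) - .predict_poly(fit, s)
  dec <- diff(p) < 0
  if (!any(dec))
    stop("central PTT curve is nowhere decreasing; cannot invert",
         call. = FALSE)
  r <- rle(dec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  # run i spans s[starts[i]] .. s[ends[i] + 1]
  overlap <- pmin(s[pmin(ends[cand] + 1L, length(s))], hi) -
    pmax(s[starts[cand]], lo)
  if (max(overlap) <= 0)
    stop("central PTT curve is not decreasing over the working SBP range",
         call. = FALSE)
  best <- cand[which.max(overlap)]
  a <- starts[best]
  b <- ends[best] + 1L
  if (s[a] > lo + 1e-6 || s[b] < hi - 1e-6)
    warning("central PTT curve is invertible only over [",
            round(s[a], 1), ", ", round(s[b], 1), "] mmHg")
  list(sbp = s[a:b], ptt = p[a:b])
}

# residual SD of the fit at given SBP values (pooled or interpolated bins)
.fit_sd_at <- function(fit, sbp, source = c("pooled", "binned")) {
  source <- match.arg(source)
  if (source == "pooled" || nrow(fit$bins) < 2L)
    return(rep(fit$residual_sd, length(sbp)))
  stats::approx(fit$bins$sbp, fit$bins$sd, xout = sbp, rule = 2)$y
}

#' PTT confidence bands and induced SBP measurement uncertainty
#'
#' The model curve is the device's PAT/SBP relation; subtracting the fitted
#' PEP gives the central transit-time curve `ptt(sbp) = pat(sbp) -
#' pep_fit(sbp)`.  Uncertainty about the PEP (its residual SD around the
#' fit) widens the transit-time curve into 1-SD and 2-SD bands, and mapping
#' each band edge back through the inverted central curve gives the SBP
#' error a device would make when estimating, rather than measuring, the
#' PEP.
#'
#' @param model a [pwv_bp_model()].
#' @param fit a [fit_pep_sbp()] result.
#' @param sbp_grid evaluation grid in mmHg (default 100-180 in 1 mmHg
#'   steps); points outside the joint support are dropped with a warning.
#' @param sd_source `"pooled"` (default) or `"binned"` residual SDs.
#' @param sd_scale multiplier on the residual SD (for sensitivity
#'   analyses).
#' @return Object of class `uncertainty_band`: a data frame with the grid,
#'   central PAT/PTT, band edges at 1 and 2 SD, the implied SBP error
#'   bounds, and the PEP fraction of PAT.
#' @export
build_uncertainty_band <- function(model, fit, sbp_grid = seq(100, 180, by = 1),
                                   sd_source = c("pooled", "binned"),
                                   sd_scale = 1) {
  stopifnot(inherits(model, "pwv_bp_model"), inherits(fit, "pep_sbp_fit"))
  sd_source <- match.arg(sd_source)
  if (sd_scale < 0) stop("sd_scale must be non-negative", call. = FALSE)

  lo <- max(model$sbp_support[1], fit$support[1])
  hi <- min(model$sbp_support[2], fit$support[2])
  keep <- sbp_grid >= lo & sbp_grid <= hi
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " grid point(s) outside the joint support")
    sbp_grid <- sbp_grid[keep]
  }
  if (length(sbp_grid) == 0L) stop("empty grid after clipping", call. = FALSE)

  pep_c <- predict(fit, sbp_grid)
  pat_c <- ptt_at(model, sbp_grid)         # model curve = device PAT relation
  ptt_c <- pat_c - pep_c
  if (any(ptt_c <= 0))
    stop("fitted PEP exceeds the model arrival time; incompatible model/fit",
         call. = FALSE)
  sdv <- .fit_sd_at(fit, sbp_grid, sd_source) * sd_scale

  # invert the central PTT curve; the curve is extended (polynomial
  # extrapolation) over the model support so band edges near the grid ends
  # remain invertible, and clipped with a warning only beyond that
  dense <- .dense_ptt_curve(model, fit, lo, hi)
  inside <- sbp_grid >= min(dense$sbp) & sbp_grid <= max(dense$sbp)
  if (!all(inside)) {
    warning("dropping ", sum(!inside),
            " grid point(s) outside the invertible range")
    sbp_grid <- sbp_grid[inside]
    pep_c <- pep_c[inside]; pat_c <- pat_c[inside]
    ptt_c <- ptt_c[inside]; sdv <- sdv[inside]
  }
  inv <- function(ptt) {
    clip <- ptt < min(dense$ptt) | ptt > max(dense$ptt)
    if (any(clip))
      warning("band edge outside the invertible range; clipped to support")
    val <- stats::approx(dense$ptt, dense$sbp,
                         xout = pmin(pmax(ptt, min(dense$ptt)),
                                     max(dense$ptt)))$y
    list(val = val, clipped = clip)
  }

  band <- data.frame(sbp = sbp_grid, pat_central = pat_c, ptt_central = ptt_c,
                     pep_central = pep_c, pep_sd = sdv)
  for (z in c(1, 2)) {
    up <- ptt_c + z * sdv   # true PEP below the fit -> more transit time
    dn <- ptt_c - z * sdv
    lo_e <- inv(up)
    hi_e <- inv(dn)
    band[[paste0("ptt_lo_", z, "sd")]] <- dn
    band[[paste0("ptt_hi_", z, "sd")]] <- up
    band[[paste0("sbp_lo_", z, "sd")]] <- lo_e$val
    band[[paste0("sbp_hi_", z, "sd")]] <- hi_e$val
    band[[paste0("sbp_err_width_", z, "sd")]] <- hi_e$val - lo_e$val
    band[[paste0("clipped_", z, "sd")]] <- lo_e$clipped | hi_e$clipped
  }
  band$pep_fraction_of_pat <- pep_c / pat_c
  structure(band, class = c("uncertainty_band", "data.frame"),
            sd_source = sd_source, sd_scale = sd_scale)
}

#' @export
print.uncertainty_band <- function(x, ...) {
  cat("<uncertainty_band> ", nrow(x), " grid points, SBP ",
      min(x$sbp), "-", max(x$sbp), " mmHg\n", sep = "")
  cat(sprintf("  PEP fraction of PAT: %.2f-%.2f | 2-SD SBP error width: %.1f-%.1f mmHg\n",
              min(x$pep_fraction_of_pat), max(x$pep_fraction_of_pat),
              min(x$sbp_err_width_2sd), max(x$sbp_err_width_2sd)))
  invisible(x)
}

#' Compare PEP-handling strategies for PAT-based SBP estimation
#'
#' Simulates the (true SBP, measured PAT) pairs implied by the cohort's
#' measurements - the arrival time is the central transit time at the true
#' pressure plus the subject's actual PEP - and inverts them back to
#' pressure under three strategies: `estimate` (assume the population PEP
#' fit, i.e. invert the PAT curve directly), `neglect` (treat the whole
#' arrival time as transit time) and `calibrate` (subtract the subject's
#' resting PEP).  Out-of-support inversions are clipped to the support edge,
#' which caps, never inflates, the reported error.
#'
#' @param model a [pwv_bp_model()].
#' @param fit a [fit_pep_sbp()] result.
#' @param measurements measurement table with `subject_id`, `phase`, `pep`,
#'   `sbp`.
#' @return A list with `summary` (per-strategy median, mean, IQR and 90th
#'   percentile of the absolute SBP error, mmHg) and `errors` (named list of
#'   per-measurement absolute errors).
#' @export
compare_neglect_vs_estimate <- function(model, fit, measurements) {
  stopifnot(inherits(model, "pwv_bp_model"), inherits(fit, "pep_sbp_fit"))
  m <- .valid_meas(measurements)
  ref <- .rest_reference(m)
  m <- merge(m, ref[, c("subject_id", "pep_rest")], by = "subject_id")

  lo <- max(model$sbp_support[1], fit$support[1])
  hi <- min(model$sbp_support[2], fit$support[2])
  m <- m[m$sbp >= lo & m$sbp <= hi, ]
  if (nrow(m) == 0L) stop("no measurements within the joint support",
                          call. = FALSE)

  dense <- .dense_ptt_curve(model, fit, lo, hi)
  m <- m[m$sbp >= min(dense$sbp) & m$sbp <= max(dense$sbp), ]
  if (nrow(m) == 0L) stop("no measurements within the invertible range",
                          call. = FALSE)
  inv_ptt <- function(ptt)
    stats::approx(dense$ptt, dense$sbp,
                  xout = pmin(pmax(ptt, min(dense$ptt)), max(dense$ptt)))$y

  ptt_true <- stats::approx(dense$sbp, dense$ptt, xout = m$sbp)$y
  pat <- ptt_true + m$pep

  sbp_estimate <- sbp_from_ptt(model, pmin(pmax(
    pat, ptt_at(model, hi)), ptt_at(model, lo)))
  sbp_neglect <- inv_ptt(pat)
  sbp_calibrate <- inv_ptt(pat - m$pep_rest)

  errors <- list(estimate = abs(sbp_estimate - m$sbp),
                 neglect = abs(sbp_neglect - m$sbp),
                 calibrate = abs(sbp_calibrate - m$sbp))
  summary <- do.call(rbind, lapply(names(errors), function(s) {
    e <- errors[[s]]
    data.frame(strategy = s, median_abs_err = stats::median(e),
               mean_abs_err = mean(e),
               q25 = unname(stats::quantile(e, 0.25)),
               q75 = unname(stats::quantile(e, 0.75)),
               q90 = unname(stats::quantile(e, 0.90)),
               n = length(e), stringsAsFactors = FALSE)
  }))
  list(summary = summary, errors = errors)
}
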