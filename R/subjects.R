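# Subject-level latent parameters ----------------------------------------
#
# One row per subject.  Resting PEP is built from a weight effect, a direct
# female offset and a Gaussian residual; the observed female-minus-male
# difference is the sum of the direct offset and the weight path
# (-3.2 + 0.15 * (59.2 - 79.2) = -6.2 ms under the default anthropometrics).
# Resting heart rate is given a weak negative latent correlation with resting
# PEP so that the pooled rest-phase PEP~HR regression is nearly, but not
# exactly, flat.

# moments of the weight distribution implied by the config (sex mixture),
# used to centre the weight effect so E[resting PEP] equals pep$rest_mean
.weight_moments <- function(cfg) {
  n  <- cfg$cohort$n
  pm <- cfg$cohort$n_male / n
  pf <- 1 - pm
  wm <- cfg$anthropometrics$weight_male
  wf <- cfg$anthropometrics$weight_female
  mu <- pm * wm["mean"] + pf * wf["mean"]
  v  <- pm * wm["sd"]^2 + pf * wf["sd"]^2 +
    pm * (wm["mean"] - mu)^2 + pf * (wf["mean"] - mu)^2
  cov_female <- pf * pm * (wf["mean"] - wm["mean"])
  list(mean = unname(mu), var = unname(v), cov_female = unname(cov_female),
       p_female = pf)
}

# theoretical SD of latent resting PEP implied by the config
.pep_latent_sd <- function(cfg) {
  wm <- .weight_moments(cfg)
  bw <- cfg$pep$weight_coef
  dg <- cfg$pep$sex_offset_female
  v <- bw^2 * wm$var + dg^2 * wm$p_female * (1 - wm$p_female) +
    2 * bw * dg * wm$cov_female + cfg$pep$between_sd^2
  sqrt(v)
}

.make_subjects <- function(cfg) {
  n  <- as.integer(cfg$cohort$n)
  nm <- as.integer(cfg$cohort$n_male)
  nf <- n - nm
  an <- cfg$anthropometrics
  sex <- rep(c("male", "female"), c(nm, nf))
  female <- sex == "female"

  age <- numeric(n)
  age[!female] <- .rnorm_trunc(nm, an$age_male["mean"], an$age_male["sd"],
                               an$age_bounds[1], an$age_bounds[2])
  age[female]  <- .rnorm_trunc(nf, an$age_female["mean"], an$age_female["sd"],
                               an$age_bounds[1], an$age_bounds[2])

  # height and weight correlated within sex
  rho <- an$height_weight_cor
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  zw <- rho * z1 + sqrt(1 - rho^2) * z2
  height <- ifelse(female,
                   an$height_female["mean"] + an$height_female["sd"] * z1,
                   an$height_male["mean"]   + an$height_male["sd"]   * z1)
  weight <- ifelse(female,
                   an$weight_female["mean"] + an$weight_female["sd"] * zw,
                   an$weight_male["mean"]   + an$weight_male["sd"]   * zw)
  weight <- pmax(weight, 40)

  wm <- .weight_moments(cfg)
  pep_rest <- cfg$pep$rest_mean +
    cfg$pep$weight_coef * (weight - wm$mean) +
    cfg$pep$sex_offset_female * (female - wm$p_female) +
    stats::rnorm(n, 0, cfg$pep$between_sd)
  pep_rest <- pmax(pep_rest, 60)

  hrc <- cfg$heart_rate
  sd_lat <- .pep_latent_sd(cfg)
  z_pep <- if (sd_lat > 0) (pep_rest - cfg$pep$rest_mean) / sd_lat else rep(0, n)
  hr_rest <- hrc$rest_mean +
    hrc$rest_sd * (hrc$rest_pep_cor * z_pep +
                     sqrt(1 - hrc$rest_pep_cor^2) * stats::rnorm(n))
  hr_rest <- pmax(hr_rest, 45)
  hr_max <- 220 - age

  men <- cfg$mental
  reactivity <- .rnorm_trunc(n, men$reactivity_mean, men$reactivity_sd,
                             men$reactivity_bounds[1], men$reactivity_bounds[2])
  habituation <- .rnorm_trunc(n, men$habituation, men$habituation_sd,
                              men$habituation_bounds[1], men$habituation_bounds[2])
  hr_gain <- pmax(men$hr_gain_per_reactivity * reactivity +
                    stats::rnorm(n, 0, men$hr_gain_sd), 0)

  phy <- cfg$physical
  slope_het <- .rnorm_trunc(n, 1, phy$slope_het_sd,
                            phy$slope_het_bounds[1], phy$slope_het_bounds[2])
  capacity <- .rnorm_trunc(n, phy$capacity_wkg["mean"], phy$capacity_wkg["sd"],
                           phy$capacity_bounds[1], phy$capacity_bounds[2])
  # working-range PEP/HR slope under load, ms per bpm (negative)
  pep_hr_slope <- -(pep_rest * phy$slope_frac * slope_het) /
    (phy$hr_frac_stop * hr_max - hr_rest)

  qr_mean <- pmax(stats::rnorm(n, cfg$qr$mean, cfg$qr$between_sd), 15)
  sur <- cfg$surrogates
  sbp_rest <- stats::rnorm(n, sur$sbp$rest_mean, sur$sbp$rest_sd)
  dbp_rest <- stats::rnorm(n, sur$dbp$rest_mean, sur$dbp$rest_sd)

  slow_period <- stats::runif(n, cfg$pep$beat_slow_period_s[1],
                              cfg$pep$beat_slow_period_s[2])
  slow_phase <- stats::runif(n, 0, 2 * pi)

  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = sex, age = age, height = height, weight = weight,
    pep_rest_mean = pep_rest,
    pep_within_sd = rep(cfg$pep$within_sd, n),
    pep_hr_slope = pep_hr_slope,
    mental_reactivity = reactivity,
    habituation_rate = habituation,
    hr_rest = hr_rest, hr_max = hr_max,
    hr_gain_mental = hr_gain,
    slope_het = slope_het,
    capacity_wkg = capacity,
    qr_mean = qr_mean,
    sbp_rest = sbp_rest, dbp_rest = dbp_rest,
    slow_period_s = slow_period, slow_phase = slow_phase,
    stringsAsFactors = FALSE
  )
}
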