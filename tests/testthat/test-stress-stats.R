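test_that("phase summaries normalise to each subject's rest and bound the estimate", {
  co <- generate_cohort(small_config(), seed = 8, beats = "none")
  ps <- phase_summaries(co$measurements, n_boot = 200, seed = 1)

  # the rest reference itself has relative PEP exactly 1
  expect_equal(ps$rel_mean[ps$phase == "rest"], 1)
  expect_equal(ps$rel_lo[ps$phase == "rest"], 1)

  # bootstrap intervals contain the point estimate
  expect_true(all(ps$rel_lo <= ps$rel_mean + 1e-9))
  expect_true(all(ps$rel_hi >= ps$rel_mean - 1e-9))

  # mental and treading phases sit below rest
  expect_true(all(ps$rel_mean[grepl("^tsst", ps$phase)] < 1))
  expect_true(all(ps$rel_mean[grepl("^ergo_E", ps$phase)] < 1))

  # a null-effect cohort keeps relative PEP at 1 within noise
  null_cfg <- cohort_config(
    cohort = list(n = 48L, n_male = 24L),
    mental = list(reactivity_mean = 0, reactivity_sd = 0,
                  reactivity_bounds = c(0, 0)),
    physical = list(onset_frac = 0, slope_frac = 0, slope_het_sd = 0))
  co0 <- generate_cohort(null_cfg, seed = 9, beats = "none")
  ps0 <- phase_summaries(co0$measurements, n_boot = 100, seed = 1)
  expect_true(all(abs(ps0$rel_mean - 1) < 0.04))
})

test_that("surrogate correlations behave like least squares should", {
  co <- generate_cohort(small_config(), seed = 10, beats = "none")
  cs <- correlate_surrogates(co$measurements)
  expect_setequal(cs$fits$stratum, c("heather_index", "hr", "lvet", "sbp_delta"))
  expect_true(all(cs$fits$r_squared >= 0 & cs$fits$r_squared <= 1))

  # R^2 of the simple fits equals the squared Pearson correlation
  m <- co$measurements
  r <- cor(m$pep, m$heather_index)
  expect_equal(cs$fits$r_squared[cs$fits$stratum == "heather_index"], r^2)

  # a constant predictor is rejected
  m2 <- m
  m2$heather_index <- 1
  expect_error(correlate_surrogates(m2), "constant")

  # noise-free coupling gives R^2 = 1
  m3 <- m
  m3$heather_index <- 50 - 0.2 * m3$pep
  cs3 <- correlate_surrogates(m3)
  expect_equal(cs3$fits$r_squared[cs3$fits$stratum == "heather_index"], 1)
})

test_that("stratified regressions strengthen with load and respect scale equivariance", {
  co <- generate_cohort(seed = 12, beats = "none")
  sr <- stratified_hr_regression(co$measurements)
  expect_equal(sr$stratum, c("rest", "mental", "physical"))
  expect_true(all(sr$r_squared >= 0 & sr$r_squared <= 1))
  expect_true(sr$r_squared[1] < sr$r_squared[2])
  expect_true(sr$r_squared[2] < sr$r_squared[3])
  expect_true(all(sr$slope < 0))

  # adding a constant to PEP shifts intercepts only; scaling scales slopes
  m <- co$measurements
  m$pep <- m$pep + 50
  sr_shift <- stratified_hr_regression(m)
  expect_equal(sr_shift$slope, sr$slope)
  expect_equal(sr_shift$r_squared, sr$r_squared)
  m2 <- co$measurements
  m2$pep <- m2$pep * 3
  sr_scale <- stratified_hr_regression(m2)
  expect_equal(sr_scale$slope, 3 * sr$slope)
  expect_equal(sr_scale$r_squared, sr$r_squared)

  # a stratum with fewer than 3 points errors
  tiny <- co$measurements[co$measurements$state != "mental", ]
  tiny <- rbind(tiny, co$measurements[co$measurements$state == "mental", ][1:2, ])
  expect_error(stratified_hr_regression(tiny), "fewer than 3")
})

test_that("per-subject slopes match an independent refit and recover the latent slope", {
  co <- generate_cohort(small_config(), seed = 14, beats = "none")
  sl <- per_subject_slopes(co$measurements)
  expect_gt(sl$summary["sd"], 0)
  expect_lte(sl$summary["steepest"], sl$summary["flattest"])

  # each slope equals a brute-force two-pass least-squares refit
  for (id in sl$slopes$subject_id[1:6]) {
    d <- co$measurements[co$measurements$subject_id == id &
                           co$measurements$state %in%
                           c("rest", "mental", "physical"), ]
    expect_equal(sl$slopes$slope[sl$slopes$subject_id == id],
                 oracle_slope(d$hr, d$pep))
  }

  # with noise off, the physical-stratum slope is the subject's latent slope
  co0 <- generate_cohort(noiseless_config(), seed = 15, beats = "none")
  sl0 <- per_subject_slopes(co0$measurements, states = "physical", min_n = 3)
  merged <- merge(sl0$slopes, co0$subjects[, c("subject_id", "pep_hr_slope")])
  expect_equal(merged$slope, merged$pep_hr_slope, tolerance = 1e-6)

  # identical subjects give (near) identical slopes
  expect_lt(sd(merged$slope / merged$pep_hr_slope), 1e-6)
})

test_that("matched-heart-rate bins show the rest > mental > physical ordering", {
  co <- generate_cohort(seed = 16, beats = "none")
  mh <- matched_hr_contrast(co$measurements, hr_bin_width = 12)

  # bin means equal brute-force group-by averages
  m <- co$measurements[co$measurements$valid, ]
  m$state <- phase_state(m$phase)
  m <- m[m$state %in% c("rest", "mental", "physical"), ]
  m$bin <- floor(m$hr / 12) * 12
  for (i in sample(nrow(mh$bins), 8)) {
    want <- mean(m$pep[m$bin == mh$bins$bin[i] & m$state == mh$bins$state[i]])
    expect_equal(mh$bins$pep[i], want)
  }

  expect_gte(mh$ordering_frac, 0.8)
  # HR-adjusted contrasts: load states sit below rest
  expect_true(all(mh$contrasts$estimate < 0))
  expect_true(all(mh$contrasts$p_value < 0.05))

  expect_error(matched_hr_contrast(co$measurements, hr_bin_width = 0),
               "positive")
})

test_that("anthropometric covariates of resting PEP are recovered", {
  co <- generate_cohort(seed = 18, beats = "none")
  an <- covariates_and_anthropometrics(co$subjects, co$measurements)
  expect_lt(an$sex_difference_ms, 0)
  expect_true(an$r2_weight >= 0 && an$r2_weight <= 1)

  # shuffling sex labels destroys the difference (permutation null)
  set.seed(4)
  diffs <- replicate(40, {
    s <- co$subjects
    s$sex <- sample(s$sex)
    covariates_and_anthropometrics(s, co$measurements)$sex_difference_ms
  })
  expect_lt(abs(mean(diffs)), 1.5)

  # single-sex cohort: difference undefined, reported as NA
  males <- co$subjects[co$subjects$sex == "male", ]
  m_only <- co$measurements[co$measurements$subject_id %in% males$subject_id, ]
  an1 <- covariates_and_anthropometrics(males, m_only)
  expect_true(is.na(an1$sex_difference_ms))
})
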