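test_that("cohort generation is reproducible and respects the design", {
  a <- generate_cohort(seed = 11, beats = "rest")
  b <- generate_cohort(seed = 11, beats = "rest")
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$beats, b$beats)

  expect_equal(nrow(a$subjects), 71L)
  expect_equal(sum(a$subjects$sex == "male"), 34L)
  expect_equal(sum(a$subjects$sex == "female"), 37L)

  # age-predicted maximum heart rate and parameter sanity
  expect_equal(a$subjects$hr_max, 220 - a$subjects$age)
  expect_true(all(a$subjects$pep_rest_mean > 0))
  expect_true(all(a$subjects$pep_within_sd >= 0))
  expect_true(all(a$subjects$pep_hr_slope <= 0))
  expect_true(all(a$subjects$mental_reactivity >= 0 &
                    a$subjects$mental_reactivity < 1))
  expect_true(all(a$subjects$habituation_rate >= 0 &
                    a$subjects$habituation_rate <= 1))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(cohort = list(n = 0L)), "positive integer")
  expect_error(cohort_config(cohort = list(n = 10L, n_male = 12L)), "n_male")
  expect_error(cohort_config(pep = list(between_sd = -1)), "non-negative")
  expect_error(cohort_config(nonsense = list(a = 1)), "unknown configuration key")
  expect_error(cohort_config(pep = list(typo_sd = 1)), "unknown configuration key")
})

test_that("large cohorts recover the configured resting mean (law of large numbers)", {
  cfg <- cohort_config(cohort = list(n = 5000L, n_male = 2394L))
  co <- generate_cohort(cfg, seed = 7, beats = "none")
  rest <- co$measurements[co$measurements$phase == "rest", ]
  expect_lt(abs(mean(rest$pep) - 104.5), 1)
})

test_that("phase expectations follow the load model", {
  co <- generate_cohort(small_config(), seed = 3, beats = "none")
  s <- co$subjects[1, ]
  cfg <- co$config

  # no-load identity and first-question reduction
  expect_equal(simulate_phase_pep(s, "rest", config = cfg), s$pep_rest_mean)
  q1 <- simulate_phase_pep(s, "tsst_Q1", config = cfg)
  expect_equal(q1 / s$pep_rest_mean, 1 - s$mental_reactivity)

  # habituation: the mental effect shrinks monotonically across questions
  qs <- sapply(1:8, function(q)
    simulate_phase_pep(s, paste0("tsst_Q", q), config = cfg))
  expect_true(all(diff(qs) >= 0))
  expect_true(all(qs < s$pep_rest_mean))

  # monotone load-response during an ascent, recovery during a break
  lf <- seq(0, 1.1, by = 0.1)
  pe <- sapply(lf, function(l)
    simulate_phase_pep(s, "ergo_E1", load_fraction = l, config = cfg))
  expect_true(all(diff(pe) <= 0))
  br <- sapply(rev(lf), function(l)
    simulate_phase_pep(s, "ergo_B1", load_fraction = l, config = cfg))
  expect_true(all(diff(br) >= 0))

  expect_error(simulate_phase_pep(s, "ergo_E1", load_fraction = 1.5,
                                  config = cfg), "load_fraction")
  expect_error(simulate_phase_pep(s, "not_a_phase", config = cfg), "phase")
})

test_that("expected PEP is ordered rest > mental > physical at matched heart rate", {
  co <- generate_cohort(seed = 5, beats = "none")
  cfg <- co$config
  # population-level expectation at a common heart-rate elevation
  for (dhr in c(5, 10, 15, 20)) {
    mental <- mean(sapply(seq_len(nrow(co$subjects)), function(i) {
      s <- co$subjects[i, ]
      s$pep_rest_mean * (1 - s$mental_reactivity *
                           pmin(dhr / max(s$hr_gain_mental, 1e-9), 1))
    }))
    physical <- mean(sapply(seq_len(nrow(co$subjects)), function(i) {
      s <- co$subjects[i, ]
      lf <- dhr / (cfg$physical$hr_frac_stop * s$hr_max - s$hr_rest)
      simulate_phase_pep(s, "ergo_E1", load_fraction = lf, config = cfg)
    }))
    rest <- mean(co$subjects$pep_rest_mean)
    expect_gt(rest, mental)
    expect_gt(mental, physical)
  }
})

test_that("protocol structure matches the experimental design", {
  co <- generate_cohort(seed = 2, beats = "none")
  m <- co$measurements
  expect_true(all(m$phase %in% phase_levels()))

  for (id in unique(m$subject_id)[1:10]) {
    d <- m[m$subject_id == id, ]
    expect_equal(d$phase[1], "rest")
    expect_equal(sum(grepl("^tsst_Q", d$phase)), 8L)
    expect_equal(sum(grepl("^ergo_B", d$phase)), 6L)
    # weight-adapted load stepping in the first ascent
    e <- d[grepl("^ergo_E", d$phase), ]
    w <- co$subjects$weight[co$subjects$subject_id == id]
    steps <- e$load_watts / (0.4 * w)
    first_ascent <- steps[seq_len(which.max(steps))]
    expect_equal(diff(first_ascent), rep(1, length(first_ascent) - 1),
                 tolerance = 1e-9)
    # timestamps strictly increasing
    expect_true(all(diff(d$t_s) > 0))
  }

  # the heart-rate stop rule terminates the first ascent at
  # subject-specific steps, so n declines across high steps
  k_first <- sapply(split(m, m$subject_id), function(d) {
    e <- d[grepl("^ergo_E", d$phase), ]
    which.max(e$load_watts)  # index of the termination step
  })
  expect_gt(length(unique(k_first)), 1L)
  expect_lt(sum(grepl("^ergo_E10$", m$phase)), nrow(co$subjects))
  # between-subject variance far exceeds within-subject noise
  expect_gt(sd(co$subjects$pep_rest_mean), 1.2 * co$config$pep$within_sd)
})

test_that("beat series have the designed fine structure", {
  co <- generate_cohort(small_config(), seed = 21, beats = "rest")
  b <- co$beats

  expect_equal(b$pep_q, b$pep_r + b$qr_time)
  expect_true(all(b$pep_q > 0) && all(b$pep_r > 0))
  # Q-R interval: small per-subject SD, independent of heart rate
  expect_lt(max(tapply(b$qr_time, b$subject_id, sd)), 4)
  expect_lt(abs(cor(b$qr_time, b$hr)), 0.1)
  # clean default: no QC flags
  expect_false(any(flag_hr_artifacts(b)))

  expect_error(simulate_beats(co$subjects[1, ], co$measurements[1, ],
                              window_s = -5), "positive")
})

test_that("cuff curves are clean or detectably disturbed", {
  co <- generate_cohort(small_config(), seed = 4, beats = "none")
  s <- co$subjects[1, ]
  m <- co$measurements[co$measurements$subject_id == s$subject_id, ][1, ]

  clean <- simulate_cuff_curve(s, m, disturbed = FALSE, seed = 1)
  expect_true(all(clean$pressure >= 0))
  expect_true(check_cuff_curve(clean))

  bad <- simulate_cuff_curve(s, m, disturbed = TRUE, seed = 1)
  expect_true(all(bad$pressure >= 0))
  expect_false(check_cuff_curve(bad))
  # the injected rise really exceeds 8 mmHg cumulatively
  p <- bad$pressure[which.max(bad$pressure):nrow(bad)]
  expect_gt(max(p - cummin(p)), 8)
})
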