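test_that("heart-rate artifact rule flags jumps over 30% within 3 s", {
  # 70 -> 95 within 2 s is a 35.7% change
  b <- data.frame(t = c(0, 1, 2), hr = c(70, 70, 95))
  expect_equal(flag_hr_artifacts(b), c(FALSE, FALSE, TRUE))

  # constant series: nothing flagged
  b2 <- data.frame(t = 0:9, hr = rep(70, 10))
  expect_false(any(flag_hr_artifacts(b2)))

  # 70 -> 90 spread over 5 s: every pairwise comparison inside a 3-s window
  # stays below 30%
  b3 <- data.frame(t = seq(0, 5, by = 1), hr = seq(70, 90, length.out = 6))
  expect_false(any(flag_hr_artifacts(b3)))

  # boundary: exactly 30% is not "more than 30%"
  b4 <- data.frame(t = c(0, 1), hr = c(70, 91))
  expect_false(any(flag_hr_artifacts(b4)))
  b5 <- data.frame(t = c(0, 1), hr = c(70, 91.5))
  expect_equal(flag_hr_artifacts(b5), c(FALSE, TRUE))

  expect_error(flag_hr_artifacts(data.frame(t = c(2, 1), hr = c(70, 70))),
               "non-decreasing")
})

test_that("artifact scan agrees with a brute-force pairwise oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 60
    t <- cumsum(runif(n, 0.5, 1.5))
    hr <- 70 + cumsum(rnorm(n, 0, 4))
    hr[sample(n, 3)] <- hr[sample(n, 3)] * 1.45
    got <- flag_hr_artifacts(data.frame(t = t, hr = hr))
    expect_equal(got, oracle_hr_flags(t, hr))
  }
})

test_that("cuff-curve rule uses the cumulative rise with a strict threshold", {
  ramp <- data.frame(t = seq(0, 40, by = 0.1),
                     pressure = seq(160, 40, length.out = 401))
  expect_true(check_cuff_curve(ramp))

  # a 10 mmHg bump during deflation invalidates
  bump <- ramp
  bump$pressure[200:210] <- bump$pressure[200:210] + 10
  expect_false(check_cuff_curve(bump))

  # a rise of exactly 8 mmHg still passes ("more than" is strict)
  exact <- data.frame(t = 0:5, pressure = c(160, 120, 100, 108, 90, 60))
  expect_true(check_cuff_curve(exact))
  over <- data.frame(t = 0:5, pressure = c(160, 120, 100, 108.5, 90, 60))
  expect_false(check_cuff_curve(over))

  # staircase rises accumulate even when single steps stay below threshold
  stair <- data.frame(t = 0:7,
                      pressure = c(160, 100, 105, 104, 109, 108, 113, 60))
  expect_false(check_cuff_curve(stair))

  expect_error(check_cuff_curve(data.frame(t = numeric(0),
                                           pressure = numeric(0))), "empty")
})

test_that("beat averaging is a right-aligned sliding mean over valid beats", {
  b <- data.frame(t = 1:4, hr = rep(60, 4), pep_q = c(100, 102, 98, 100))
  out <- average_beats(b, 4)
  expect_equal(out$pep_q_avg, c(NA, NA, NA, 100))

  # window 1 is the identity
  expect_equal(average_beats(b, 1)$pep_q_avg, b$pep_q)

  expect_error(average_beats(b, 0), "positive integer")

  # flagged beats are excluded from every window; compare with a brute-force
  # mean over the valid subset
  set.seed(9)
  b2 <- data.frame(t = 1:30, hr = 60, pep_q = rnorm(30, 100, 5),
                   valid = rep(TRUE, 30))
  b2$valid[c(7, 15, 16)] <- FALSE
  out2 <- average_beats(b2, 4)
  expect_true(all(is.na(out2$pep_q_avg[!b2$valid])))
  vidx <- which(b2$valid)
  for (k in seq_along(vidx)) {
    if (k < 4) next
    expected <- mean(b2$pep_q[vidx[(k - 3):k]])
    expect_equal(out2$pep_q_avg[vidx[k]], expected)
  }
})

test_that("averaging white-noise beats reduces variance by about 1/window", {
  set.seed(31)
  b <- data.frame(t = seq_len(4000), hr = 60, pep_q = rnorm(4000, 100, 6))
  out <- average_beats(b, 4)
  ratio <- var(out$pep_q_avg, na.rm = TRUE) / var(b$pep_q)
  expect_equal(ratio, 1 / 4, tolerance = 0.1)
})

test_that("QC is idempotent and conserves counts", {
  cfg <- small_config(artifacts = list(beat_hr_jump_rate = 0.01,
                                       cuff_disturb_rate = 0.15))
  co <- generate_cohort(cfg, seed = 13, beats = "full", cuff_curves = TRUE)

  r1 <- qc_cohort(co)
  expect_equal(r1$report$n_input,
               r1$report$n_valid + r1$report$n_excluded_hr_artifact +
                 r1$report$n_excluded_cuff)
  expect_gt(r1$report$n_excluded_hr_artifact + r1$report$n_excluded_cuff, 0)
  # each excluded record carries exactly one primary reason
  fl <- r1$report$flags
  expect_true(all(is.na(fl$reason[fl$valid])))
  expect_true(all(!is.na(fl$reason[!fl$valid])))

  # second application changes nothing
  r2 <- qc_cohort(r1$cohort)
  expect_equal(r2$report$n_valid, r1$report$n_valid)
  expect_equal(r2$cohort$measurements$valid, r1$cohort$measurements$valid)

  # zero-artifact datasets pass unchanged
  clean <- generate_cohort(small_config(), seed = 13, beats = "rest")
  rc <- qc_cohort(clean)
  expect_equal(rc$report$n_valid, rc$report$n_input)
})

test_that("Q-wave and R-wave PEP agree up to the Q-R interval", {
  # perfect affine relation gives r = 1
  b <- data.frame(t = 1:50, hr = 60, pep_q = seq(80, 110, length.out = 50))
  b$pep_r <- b$pep_q - 30
  b$qr_time <- rep(30, 50)
  res <- compare_q_vs_r(b)
  expect_equal(res$pearson_r, 1)

  expect_error(compare_q_vs_r(b[1:2, ]), "3 beats")

  # on generated data: strong correlation, small Q-R SD, no load dependence
  co <- generate_cohort(small_config(), seed = 17, beats = "full")
  qr <- compare_q_vs_r(co$beats)
  expect_gt(qr$pearson_r, 0.9)
  expect_lt(qr$qr_sd_ms, 4)
  expect_false(is.na(qr$qr_dhr_p))
})
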