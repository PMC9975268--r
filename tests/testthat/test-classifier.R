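test_that("features are per-subject state deltas against the rest calibration", {
  m <- data.frame(
    subject_id = "A",
    phase = c("rest", "tsst_Q1", "tsst_Q2", "ergo_E1", "ergo_B2"),
    pep = c(104, 92, 88, 54, 104),
    hr = c(60, 74, 76, 120, 60),
    valid = TRUE
  )
  f <- build_features(m)
  expect_equal(nrow(f), 3L)
  expect_equal(f$d_pep[f$state == "mental"], mean(c(92, 88)) - 104)
  expect_equal(f$d_hr[f$state == "mental"], mean(c(74, 76)) - 60)
  expect_equal(f$d_pep[f$state == "physical"], 54 - 104)
  expect_equal(f$d_pep[f$state == "rest"], 0)
  expect_equal(f$d_hr[f$state == "rest"], 0)

  # a subject missing a state is excluded with a message
  m2 <- m[m$phase != "ergo_E1", ]
  expect_message(expect_error(build_features(m2), "complete"), "lacked")

  # full cohort: exactly three feature points per complete subject
  co <- generate_cohort(seed = 19, beats = "none")
  f2 <- build_features(co$measurements)
  expect_equal(nrow(f2), 3L * 71L)
  expect_equal(as.integer(table(f2$state)), rep(71L, 3))
})

test_that("the k-NN agrees with an independent naive implementation", {
  set.seed(77)
  for (rep in 1:4) {
    n <- 60
    x <- cbind(rnorm(n), rnorm(n))
    y <- factor(sample(c("rest", "mental", "physical"), n, replace = TRUE),
                levels = c("rest", "mental", "physical"))
    xt <- cbind(rnorm(25), rnorm(25))
    got <- pepstress:::.knn_predict(x, y, xt, k = 7)
    expect_equal(got, oracle_knn(x, y, xt, k = 7))
  }
})

test_that("subject-wise evaluation has no leakage and honours edge cases", {
  co <- generate_cohort(small_config(), seed = 20, beats = "none")
  f <- build_features(co$measurements)
  rep <- evaluate_knn(f, k = 5, folds = 4, repeats = 2, seed = 1)

  # folds partition subjects: each subject appears in exactly one test fold
  for (assign in rep$fold_assignments) {
    all_ids <- unlist(assign)
    expect_setequal(all_ids, unique(f$subject_id))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
  expect_true(all(rep$ppv >= 0 & rep$ppv <= 1))
  expect_true(all(rep$sensitivity >= 0 & rep$sensitivity <= 1))
  expect_equal(sum(rep$confusion), nrow(f) * rep$repeats)

  expect_error(evaluate_knn(f, k = 500), "smaller than the training-set")
})

test_that("separated clusters are classified perfectly; shuffled labels at chance", {
  set.seed(55)
  n <- 30
  f <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:n), each = 3),
    state = factor(rep(c("rest", "mental", "physical"), n),
                   levels = c("rest", "mental", "physical")),
    d_pep = rep(c(0, -40, -80), n) + rnorm(3 * n, 0, 1),
    d_hr = rep(c(0, 30, 80), n) + rnorm(3 * n, 0, 1)
  )
  rep <- evaluate_knn(f, k = 5, folds = 5, repeats = 3, seed = 2)
  expect_equal(rep$ppv_macro, 1)
  expect_equal(rep$sensitivity_macro, 1)

  # label shuffling drops sensitivity to about 1/3
  set.seed(3)
  sens <- replicate(15, {
    fs <- f
    fs$state <- sample(fs$state)
    evaluate_knn(fs, k = 5, folds = 5, repeats = 1, seed = 4)$sensitivity_macro
  })
  expect_equal(mean(sens), 1 / 3, tolerance = 0.1)
})

test_that("macro metrics are invariant to a relabelling of the classes", {
  co <- generate_cohort(small_config(), seed = 23, beats = "none")
  f <- build_features(co$measurements)
  base <- evaluate_knn(f, k = 5, folds = 4, repeats = 3, seed = 6)

  # bijective relabelling: rest->mental->physical->rest
  perm <- c(rest = "mental", mental = "physical", physical = "rest")
  f2 <- f
  f2$state <- factor(unname(perm[as.character(f$state)]),
                     levels = c("rest", "mental", "physical"))
  swapped <- evaluate_knn(f2, k = 5, folds = 4, repeats = 3, seed = 6)
  expect_equal(swapped$ppv_macro, base$ppv_macro, tolerance = 1e-12)
  expect_equal(swapped$sensitivity_macro, base$sensitivity_macro,
               tolerance = 1e-12)
})

test_that("the decision map is deterministic and anchored at the calibration origin", {
  co <- generate_cohort(seed = 24, beats = "none")
  f <- build_features(co$measurements)
  grid <- decision_map(f, k = 13, d_hr_range = c(-10, 90),
                       d_pep_range = c(-70, 15), n = 31)

  origin <- grid[which.min(grid$d_hr^2 + grid$d_pep^2), ]
  expect_equal(as.character(origin$state), "rest")
  corner <- grid[which.max(grid$d_hr - grid$d_pep), ]
  expect_equal(as.character(corner$state), "physical")
  # boundaries are not axis-parallel-only: PEP matters at fixed HR
  mid <- grid[abs(grid$d_hr - 30) < 2, ]
  expect_gt(length(unique(mid$state)), 1L)

  # invariant to shuffling the training-point order
  set.seed(10)
  f_shuf <- f[sample(nrow(f)), ]
  grid2 <- decision_map(f_shuf, k = 13, d_hr_range = c(-10, 90),
                        d_pep_range = c(-70, 15), n = 31)
  expect_equal(grid$state, grid2$state)

  expect_error(decision_map(f, n = 1), "at least 2")
})
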