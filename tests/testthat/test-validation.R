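test_that("rank-based AUC matches pair enumeration and ROC area", {
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auc_mann_whitney(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_mann_whitney(1:5, rep(1, 5)), "both classes")
  # equivalence with the trapezoidal ROC area for tie-free scores
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    s <- rnorm(n)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mann_whitney(s, y), roc_trapezoid(s, y),
                 tolerance = 1e-12)
  }
})

test_that("DeLong variance matches an explicit double-loop computation", {
  # n = 12 fixture with ties
  scores <- c(0.1, 0.35, 0.2, 0.8, 0.35, 0.6, 0.45, 0.9, 0.15, 0.55,
              0.35, 0.7)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1, 0, 0, 1, 1)
  dl <- delong_ci(scores, y)
  cases <- scores[y == 1]; controls <- scores[y == 0]
  m <- length(cases); n <- length(controls)
  v10 <- numeric(m); v01 <- numeric(n)
  for (i in seq_len(m)) {
    acc <- 0
    for (j in seq_len(n)) {
      acc <- acc + (cases[i] > controls[j]) + 0.5 * (cases[i] == controls[j])
    }
    v10[i] <- acc / n
  }
  for (j in seq_len(n)) {
    acc <- 0
    for (i in seq_len(m)) {
      acc <- acc + (cases[i] > controls[j]) + 0.5 * (cases[i] == controls[j])
    }
    v01[j] <- acc / m
  }
  expect_equal(dl$auc, mean(v10))
  expect_equal(dl$variance, var(v10) / m + var(v01) / n, tolerance = 1e-12)
  expect_gte(dl$variance, 0)
  expect_true(dl$lo <= dl$auc && dl$auc <= dl$hi)
})

test_that("DeLong interval degenerates to a point at AUC 1 and is symmetric", {
  s <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  dl <- delong_ci(s, y)
  expect_equal(dl$variance, 0)
  expect_equal(c(dl$lo, dl$hi), c(1, 1))
  # negating scores and flipping labels preserves the interval
  set.seed(8)
  s2 <- rnorm(40); y2 <- rbinom(40, 1, 0.5)
  a <- delong_ci(s2, y2)
  b <- delong_ci(-s2, 1 - y2)
  expect_equal(a$auc, b$auc)
  expect_equal(a$variance, b$variance)
  expect_equal(c(a$lo, a$hi), c(b$lo, b$hi))
  expect_error(delong_ci(1:5, c(1, 0, 0, 0, 0)), "at least 2")
})

test_that("DeLong agrees with pROC on a random dataset", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- rnorm(60); y <- rbinom(60, 1, 0.4)
  dl <- delong_ci(s, y)
  ci <- suppressMessages(pROC::ci.auc(y, s, method = "delong",
                                      direction = "<", quiet = TRUE))
  expect_equal(dl$auc, as.numeric(ci[2]), tolerance = 1e-10)
  expect_equal(dl$lo, max(0, as.numeric(ci[1])), tolerance = 1e-10)
  expect_equal(dl$hi, min(1, as.numeric(ci[3])), tolerance = 1e-10)
})

test_that("B = 0 validation reports apparent metrics unchanged", {
  d <- random_logit_data(100, c(-1, 1, -1), seed = 2)
  rep0 <- bootstrap_validate(d$X, d$y, B = 0)
  expect_equal(rep0$optimism, 0)
  expect_equal(rep0$corrected_auc, rep0$apparent_auc)
  expect_equal(rep0$calibration_slope, 1)
  expect_equal(rep0$calibration_intercept, 0)
})

test_that("bootstrap validation is reproducible under a fixed seed", {
  d <- random_logit_data(80, c(-1, 0.8), seed = 5)
  a <- bootstrap_validate(d$X, d$y, B = 40, seed = 123)
  b <- bootstrap_validate(d$X, d$y, B = 40, seed = 123)
  expect_identical(a, b)
  c_ <- bootstrap_validate(d$X, d$y, B = 40, seed = 124)
  expect_false(identical(a$optimism, c_$optimism))
})

test_that("optimism is positive for an overfit many-predictor model", {
  set.seed(31)
  X <- matrix(rnorm(60 * 20), 60, 20,
              dimnames = list(NULL, paste0("noise", 1:20)))
  y <- rbinom(60, 1, 0.4)
  rep_over <- suppressWarnings(bootstrap_validate(X, y, B = 60, seed = 7))
  expect_gt(rep_over$optimism, 0)
  expect_lt(rep_over$corrected_auc, rep_over$apparent_auc)
  # slope < 1 indicates the overfitting the optimism measures
  expect_lt(rep_over$calibration_slope, 1)
})

test_that("calibration curve is near-ideal for well-calibrated predictions", {
  set.seed(17)
  p <- runif(3000, 0.02, 0.95)
  y <- rbinom(3000, 1, p)
  cc <- calibration_curve(p, y)
  expect_lt(cc$mae, 0.03)
  # constant predictions at the event rate calibrate to a point
  y2 <- rbinom(500, 1, 0.3)
  cc2 <- calibration_curve(rep(mean(y2), 500), y2)
  expect_lt(cc2$mae, 1e-10)
  # anti-calibrated predictions show large error
  cc3 <- calibration_curve(1 - p, y)
  expect_gt(cc3$mae, 0.2)
  expect_error(calibration_curve(runif(10), rbinom(10, 1, 0.5)),
               "at least 20")
  # binned variant agrees loosely with the smoother
  cc4 <- calibration_curve(p, y, method = "bins")
  expect_lt(cc4$mae, 0.05)
})

test_that("recalibration recovers slope 1, intercept 0 for a true model", {
  d <- random_logit_data(4000, c(-1.2, 1, -0.7), seed = 23)
  f <- fit_logistic(d$X, d$y)
  rep_v <- bootstrap_validate(d$X, d$y, B = 30, seed = 3)
  expect_equal(rep_v$calibration_slope, 1, tolerance = 0.1)
  expect_equal(rep_v$calibration_intercept, 0, tolerance = 0.1)
  expect_equal(rep_v$corrected_auc, rep_v$apparent_auc, tolerance = 0.02)
})
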