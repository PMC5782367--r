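test_that("period assignment uses closed intervals [10,20] and [30,40]", {
  expect_equal(assign_periods(c(15, 25, 40, 9, 10, 20, 21, 29, 30)),
               c("early", "neither", "late", "neither", "early", "early",
                 "neither", "neither", "late"))
})

test_that("observation selection keeps last across periods, first within", {
  occ <- data.frame(patient_id = c("A", "A"), icu_day = c(12, 32))
  sel <- select_observations(occ)
  expect_equal(sel$selected$icu_day, 32)

  occ2 <- data.frame(patient_id = c("B", "B"), icu_day = c(11, 19))
  sel2 <- select_observations(occ2)
  expect_equal(sel2$selected$icu_day, 11)

  fx <- selection_fixture()
  self <- select_observations(fx)
  expect_equal(unname(self$group_sizes), c(10, 9))
  expect_lte(max(table(self$selected$patient_id)), 1)
})

test_that("Mann-Whitney: exact enumeration, ties, and wilcox.test agreement", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)   # 2 of the 20 assignments are as extreme
  expect_equal(mw$method, "exact")

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  deg <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  # agreement with stats::wilcox.test as the independent reference
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(6, 0.5)
    mw <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-12)
  }
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(12, 0.3)
    mw <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney p is invariant under monotone transforms of the data", {
  set.seed(10)
  x <- rlnorm(7); y <- rlnorm(8, 0.4)
  p0 <- mann_whitney(x, y)$p_value
  expect_equal(mann_whitney(log(x), log(y))$p_value, p0)
  expect_equal(mann_whitney(rank(c(x, y))[1:7], rank(c(x, y))[8:15])$p_value, p0)
})

test_that("random-intercept fit recovers a deterministic line exactly", {
  day <- c(10, 18, 30, 12, 22, 40, 15, 33)
  pid <- c("a", "b", "c", "d", "e", "f", "g", "h")
  y <- 2 + 0.5 * day
  fit <- fit_random_intercept(y, day, pid)
  expect_equal(fit$beta1, 0.5, tolerance = 1e-9)
  expect_equal(fit$beta0, 2, tolerance = 1e-8)
  expect_equal(fit$sigma_e, 0, tolerance = 1e-6)
  expect_true(fit$boundary || fit$sigma_b < 1e-6)
})

test_that("with no between-patient variance the slope matches OLS", {
  set.seed(11)
  day <- rep(c(10, 20, 30, 40), times = 6)
  pid <- rep(letters[1:6], each = 4)
  y <- 5 - 0.3 * day + rnorm(length(day), sd = 2)  # sigma_b = 0 truth
  fit <- fit_random_intercept(y, day, pid)
  ols <- lm(y ~ day)
  expect_equal(fit$beta1, unname(coef(ols)[2]), tolerance = 1e-4)
})

test_that("balanced two-day design with sigma_b = 0 reduces to the mean contrast", {
  set.seed(12)
  day <- rep(c(10, 30), times = 10)
  pid <- paste0("p", seq_along(day))  # one obs per patient: no pairing
  y <- 4 + 0.2 * day + rnorm(20, sd = 1)
  fit <- fit_random_intercept(y, day, pid)
  closed_form <- (mean(y[day == 30]) - mean(y[day == 10])) / 20
  expect_equal(fit$beta1, closed_form, tolerance = 1e-6)
})

test_that("sensitivity refit removes exactly the planted outlier patient", {
  set.seed(13)
  day <- rep(c(10, 20, 30), times = 10)
  pid <- rep(sprintf("p%02d", 1:10), each = 3)
  y <- 1 + 0.1 * day + rnorm(30, sd = 1)
  fit <- fit_random_intercept(y, day, pid)
  s0 <- sensitivity_refit(fit)
  expect_length(s0$removed_patient_ids, 0)
  expect_identical(s0$refit$beta1, fit$beta1)

  y_out <- y
  y_out[pid == "p07"][2] <- y_out[pid == "p07"][2] + 10 * sd(fit$residuals) * 3
  fit2 <- fit_random_intercept(y_out, day, pid)
  s2 <- sensitivity_refit(fit2)
  expect_equal(s2$removed_patient_ids, "p07")
  expect_equal(s2$refit$n_patients, 9)
})

test_that("zero-crossing day is -beta0/beta1 with a delta-method SE", {
  fit <- structure(list(beta0 = -35, beta1 = 1,
                        vcov_fixed = diag(c(4, 0.01))),
                   class = "cohort_trend")
  zc <- zero_crossing_day(fit)
  expect_equal(zc$day, 35)
  # gradient (-1/b1, b0/b1^2) = (-1, -35): var = 4 + 35^2 * 0.01
  expect_equal(zc$se, sqrt(4 + 35^2 * 0.01))

  fit$beta1 <- 0
  expect_true(zero_crossing_day(fit)$undefined)
})

test_that("period comparison reports medians, quartiles and group sizes", {
  fx <- selection_fixture()
  pc <- period_comparison(fx, "value")
  expect_equal(unname(pc$group_sizes), c(10, 9))
  sel <- select_observations(fx)$selected
  expect_equal(pc$early$median, median(sel$value[sel$period == "early"]))
  expect_equal(pc$late$n, 9)
  expect_true(pc$p_value >= 0 && pc$p_value <= 1)
})
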