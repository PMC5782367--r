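test_that("a well-formed single-occasion cohort validates and counts", {
  ch <- minimal_cohort()
  expect_s3_class(ch, "lt_cohort")
  expect_equal(nrow(ch$occasions), 1)
  expect_equal(nrow(ch$samples), 8)
})

test_that("domain violations are rejected with errors naming the problem", {
  tabs <- minimal_cohort_tables()

  bad <- tabs; bad$samples$minute[1] <- 130L
  err <- expect_error(do.call(as_cohort, bad), class = "lt_validation_error")
  expect_match(conditionMessage(err), "135,140,145,150")

  bad <- tabs; bad$occasions$hematocrit <- 1.2
  expect_error(do.call(as_cohort, bad), class = "lt_validation_error")

  bad <- tabs; bad$samples$phe_ttr[1] <- 1.5
  expect_error(do.call(as_cohort, bad), class = "lt_validation_error")

  bad <- tabs; bad$samples <- rbind(bad$samples, bad$samples[1, ])
  expect_error(do.call(as_cohort, bad), class = "lt_integrity_error")

  bad <- tabs; bad$samples$phe <- NULL
  err <- expect_error(do.call(as_cohort, bad), class = "lt_schema_error")
  expect_match(conditionMessage(err), "phe")

  bad <- tabs; bad$plethysmography$slope_pct_per_min[1] <- -0.5
  expect_error(do.call(as_cohort, bad), class = "lt_validation_error")
})

test_that("validation rejects perturbations outside each field's domain", {
  set.seed(41)
  tabs <- minimal_cohort_tables()
  perturb <- list(
    function(t) { t$occasions$hematocrit <- sample(c(0, 1, -0.1, 1.7), 1); t },
    function(t) { t$occasions$icu_day <- sample(c(0, -3, 2.5), 1); t },
    function(t) { t$patients$age <- -sample(1:80, 1); t },
    function(t) { t$patients$bmi <- 0; t },
    function(t) { t$samples$ala[2] <- -runif(1, 1, 50); t },
    function(t) { t$samples$mh3_ttr[3] <- runif(1, 1, 2); t },
    function(t) { t$biopsies$phe_ttr_muscle <- runif(1, 1, 2); t },
    function(t) { t$samples$site[1] <- "capillary"; t },
    function(t) { t$patients$diagnosis_class <- "trauma"; t })
  for (f in perturb) {
    for (rep in 1:3) {
      expect_error(do.call(as_cohort, f(tabs)), class = "lt_error")
    }
  }
})

test_that("write/load round trip is the identity on all numeric fields", {
  sim <- generate_cohort(seed = 11)
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir)
  back <- load_cohort(dir)
  for (tab in c("occasions", "samples", "biopsies", "plethysmography")) {
    a <- sim$cohort[[tab]]; b <- back[[tab]]
    expect_identical(names(a), names(b))
    for (col in names(a)) {
      if (is.numeric(a[[col]])) {
        expect_identical(b[[col]], as.vector(a[[col]]),
                         label = paste(tab, col))
      }
    }
  }
})

test_that("occasion averaging takes plain means and ignores timepoint order", {
  ch <- minimal_cohort()
  av <- average_occasion(ch$samples, ch$biopsies,
                         occasion_flow(rep(3 / 0.7, 10), rep(3 / 0.7, 10), 0.30))
  expect_equal(av$Ca, 60)
  expect_equal(av$Em, 0.04)
  expect_equal(av$PF, 3)

  sam <- ch$samples
  sam$phe[sam$site == "artery"] <- c(58, 60, 62, 60)
  av2 <- average_occasion(sam, ch$biopsies, 3)
  expect_equal(av2$Ca, 60)

  shuffled <- sam[sample(nrow(sam)), ]
  av3 <- average_occasion(shuffled, ch$biopsies, 3)
  expect_equal(av3[c("Ca", "Cv", "Ea", "Ev", "Ca3", "Cv3", "Ea3", "Ev3")],
               av2[c("Ca", "Cv", "Ea", "Ev", "Ca3", "Cv3", "Ea3", "Ev3")])
})

test_that("incomplete occasions error by default, warn when configured", {
  ch <- minimal_cohort()
  sam <- ch$samples[-1, ]  # artery down to 3 timepoints
  expect_error(average_occasion(sam, ch$biopsies, 3),
               class = "lt_incomplete_occasion_error")
  cfg <- lt_config(qc = list(min_timepoints = 2))
  expect_warning(av <- average_occasion(sam, ch$biopsies, 3, cfg),
                 "timepoint")
  expect_equal(av$Cv, 65)
})

test_that("steady-state QC computes CV per series and flags instability", {
  ch <- minimal_cohort()
  qc <- steady_state_qc(ch$samples)
  expect_true(all(qc$cv == 0))
  expect_false(any(qc$flag))

  sam <- ch$samples
  sam$phe[sam$site == "artery"] <- c(1, 1, 1, 2)
  qc2 <- steady_state_qc(sam)
  row <- qc2[qc2$site == "artery" & qc2$analyte == "phe", ]
  expect_equal(row$cv, 0.4)
  expect_true(row$flag)

  sam$phe[sam$site == "artery"] <- 0
  qc3 <- steady_state_qc(sam)
  row <- qc3[qc3$site == "artery" & qc3$analyte == "phe", ]
  expect_true(row$degenerate)
  expect_true(row$flag)
})

test_that("QC flags are rare at the generator's default enrichment noise", {
  set.seed(42)
  # 2% CV lognormal series of 4, per analyte: the 15% CV flag should
  # essentially never fire (simulation oracle at 1000 occasions).
  n_flag <- 0L
  for (i in 1:1000) {
    v <- 0.06 * rlnorm(4, -0.5 * log(1 + 0.02^2), sqrt(log(1 + 0.02^2)))
    if (sd(v) / mean(v) > 0.15) n_flag <- n_flag + 1L
  }
  expect_lt(n_flag / 1000, 0.01)
})

test_that("TTR / mole-percent-excess conversions invert each other", {
  ttr <- c(0.001, 0.04, 0.08, 0.5)
  expect_equal(mpe_to_ttr(ttr_to_mpe(ttr)), ttr)
  expect_equal(ttr_to_mpe(0.08), 100 * 0.08 / 1.08)
})
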