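test_that("forward model inverts the worked example exactly", {
  fwd <- forward_occasion(S = 67.5, B = 82.5, F_MA = 82.5, PF = 3,
                          Ca = 60, Ea = 0.08)
  expect_equal(fwd$Cv, 65)
  expect_equal(fwd$Em, 0.04)
  expect_equal(fwd$Ev, 0.06)

  # zero balance: no arteriovenous gradient
  fwd0 <- forward_occasion(S = 80, B = 80, F_MA = 80, PF = 3, Ca = 60, Ea = 0.08)
  expect_equal(fwd0$Cv, 60)

  expect_error(forward_occasion(S = 60, B = 80, F_MA = 500, PF = 3,
                                Ca = 60, Ea = 0.08),
               class = "lt_generation_error")
  expect_error(forward_occasion(S = 100, B = 50, F_MA = 40, PF = 3,
                                Ca = 60, Ea = 0.08),
               class = "lt_generation_error")
})

test_that("three-pool analysis inverts the forward model on random truths", {
  set.seed(303)
  truths <- random_valid_truth(12000)
  expect_gte(nrow(truths), 10000)
  fwd <- with(truths, {
    NB <- S - B
    F_VM <- F_MA - NB
    F_VA <- Ca * PF - F_MA
    Em <- Ea * F_MA / (F_MA + B)
    Cv <- Ca - NB / PF
    Ev <- (F_VA * Ea + F_VM * Em) / (Cv * PF)
    data.frame(Cv, Ev, Em)
  })
  expect_true(all(fwd$Em < fwd$Ev & fwd$Ev < truths$Ea))
  err <- vapply(seq_len(nrow(truths)), function(i) {
    av <- list(Ca = truths$Ca[i], Cv = fwd$Cv[i], Ea = truths$Ea[i],
               Ev = fwd$Ev[i], Em = fwd$Em[i], PF = truths$PF[i])
    th <- three_pool(av)
    max(abs(th$F_0M - truths$S[i]) / truths$S[i],
        abs(th$F_M0 - truths$B[i]) / truths$B[i])
  }, numeric(1))
  expect_lt(max(err), 1e-9)
})

test_that("recycling dominance: three-pool rates bound two-pool rates", {
  set.seed(304)
  truths <- random_valid_truth(12000)
  expect_gte(nrow(truths), 10000)
  gaps <- t(vapply(seq_len(nrow(truths)), function(i) {
    tr <- truths[i, ]
    fwd <- forward_occasion(tr$S, tr$B, tr$F_MA, tr$PF, tr$Ca, tr$Ea)
    av <- list(Ca = tr$Ca, Cv = fwd$Cv, Ea = tr$Ea, Ev = fwd$Ev,
               Em = fwd$Em, PF = tr$PF)
    recycling_gap(two_pool(av), three_pool(av))
  }, numeric(2)))
  expect_true(all(gaps >= -1e-9))
  expect_lt(max(abs(gaps[, 1] - gaps[, 2]) / pmax(abs(gaps[, 1]), 1)), 1e-9)
})

test_that("cohort generation is deterministic in the seed and schedules 1-3 occasions", {
  s1 <- generate_cohort(seed = 21)
  s2 <- generate_cohort(seed = 21)
  expect_identical(s1$cohort$samples, s2$cohort$samples)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_cohort(seed = 22)
  expect_false(identical(s1$cohort$samples, s3$cohort$samples))

  counts <- table(s1$cohort$occasions$patient_id)
  expect_true(all(counts >= 1 & counts <= 3))
  expect_true(all(s1$cohort$occasions$icu_day >= 10 &
                  s1$cohort$occasions$icu_day <= 40))
  expect_error(generate_cohort(sim_config()), class = "lt_config_error")
})

test_that("written simulations round-trip through the loader byte-identically", {
  sim <- generate_cohort(seed = 23)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- load_cohort(dir)
  expect_equal(back$samples$phe, sim$cohort$samples$phe)
  run1 <- file.path(dir, "again")
  write_simulation(generate_cohort(seed = 23), run1)
  expect_identical(readLines(file.path(dir, "samples.csv")),
                   readLines(file.path(run1, "samples.csv")))
})

test_that("noise-free generation is recovered exactly by the full pipeline", {
  cfg <- lt_config(simulate = list(cv_conc = 0, cv_enrich = 0, cv_flow = 0))
  sim <- generate_cohort(do.call(sim_config, cfg$simulate), seed = 31)
  an <- analyze_cohort(sim$cohort, cfg)
  m <- merge(an$kinetics, sim$truth, by = c("patient_id", "icu_day"))
  expect_equal(nrow(m), nrow(sim$truth))
  expect_lt(max(abs(m$F_0M - m$S) / abs(m$S)), 1e-9)
  expect_lt(max(abs(m$F_M0 - m$B) / abs(m$B)), 1e-9)
  expect_lt(max(abs(m$PF.x - m$PF.y) / m$PF.y), 1e-9)
  expect_lt(max(abs(m$Ra3.x - m$Ra3.y) / m$Ra3.y), 1e-9)
  expect_lt(max(abs(m$NB.x - m$NB.y) / pmax(abs(m$NB.y), 1)), 1e-9)
  # per-amino-acid fluxes, including glutamate uptake
  aa <- an$aaflux[an$aaflux$aa != "total", ]
  for (code in unique(aa$aa)) {
    est <- aa$flux[aa$aa == code]
    tru <- m[[paste0("flux_", code)]][match(
      paste(aa$patient_id[aa$aa == code], aa$icu_day[aa$aa == code]),
      paste(m$patient_id, m$icu_day))]
    expect_lt(max(abs(est - tru) / pmax(abs(tru), 1e-6)), 1e-9)
  }
})

test_that("generated enrichments always respect Em < Ev < Ea", {
  sim <- generate_cohort(seed = 33)
  art <- sim$cohort$samples[sim$cohort$samples$site == "artery", ]
  ven <- sim$cohort$samples[sim$cohort$samples$site == "vein", ]
  Ea <- tapply(art$phe_ttr, paste(art$patient_id, art$icu_day), mean)
  Ev <- tapply(ven$phe_ttr, paste(ven$patient_id, ven$icu_day), mean)
  bio <- sim$cohort$biopsies
  Em <- setNames(bio$phe_ttr_muscle, paste(bio$patient_id, bio$icu_day))
  keys <- names(Ea)
  expect_true(all(Em[keys] < Ev[keys] & Ev[keys] < Ea[keys]))
})
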