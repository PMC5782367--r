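# Fixtures built in code: a minimal valid one-occasion cohort, the
# worked-example occasion averages, and the observation-selection cohort.

worked_example_averages <- function() {
  list(Ca = 60, Cv = 65, Ea = 0.08, Ev = 0.06, Em = 0.04, PF = 3,
       Ca3 = 5, Cv3 = 6, Ea3 = 0.05, Ev3 = 0.04)
}

# One patient, one occasion, 4 timepoints x 2 sites, constant values.
minimal_cohort_tables <- function() {
  patients <- data.frame(patient_id = "P01", sex = "M", age = 65, bmi = 26,
                         admission_weight = 82, diagnosis_class = "surgical",
                         stringsAsFactors = FALSE)
  occasions <- data.frame(patient_id = "P01", icu_day = 10, hematocrit = 0.30,
                          sofa = 6, kcal_per_kg_day = 20, aa_g_per_kg_day = 1,
                          stringsAsFactors = FALSE)
  grid <- expand.grid(minute = c(135L, 140L, 145L, 150L),
                      site = c("artery", "vein"),
                      stringsAsFactors = FALSE)
  samples <- data.frame(patient_id = "P01", icu_day = 10,
                        minute = grid$minute, site = grid$site,
                        phe_ttr = ifelse(grid$site == "artery", 0.08, 0.06),
                        mh3_ttr = ifelse(grid$site == "artery", 0.05, 0.04),
                        stringsAsFactors = FALSE)
  for (aa in aa_panel_default()) {
    samples[[aa]] <- ifelse(grid$site == "artery", 100, 105)
  }
  samples$phe <- ifelse(grid$site == "artery", 60, 65)
  samples$mh3 <- ifelse(grid$site == "artery", 5, 6)
  biopsies <- data.frame(patient_id = "P01", icu_day = 10,
                         phe_ttr_muscle = 0.04, stringsAsFactors = FALSE)
  pleth <- expand.grid(phase = c("pre", "post"), reading_index = 1:10,
                       stringsAsFactors = FALSE)
  plethysmography <- data.frame(patient_id = "P01", icu_day = 10,
                                phase = pleth$phase,
                                reading_index = pleth$reading_index,
                                slope_pct_per_min = 3 / 0.7,
                                stringsAsFactors = FALSE)
  list(patients = patients, occasions = occasions, samples = samples,
       biopsies = biopsies, plethysmography = plethysmography)
}

minimal_cohort <- function() {
  tabs <- minimal_cohort_tables()
  as_cohort(tabs$patients, tabs$occasions, tabs$samples, tabs$biopsies,
            tabs$plethysmography)
}

# Occasion schedule mirroring the study's statistics description:
# 20 patients, studied 1 (n = 10), 2 (n = 9) or 3 (n = 1) times; one
# patient in both comparison periods, two patients twice within one
# period; keep-last / keep-first selection must yield groups of 10 and 9.
selection_fixture <- function() {
  occ <- rbind(
    # singles: 5 early, 4 late, 1 between periods
    data.frame(patient_id = sprintf("P%02d", 1:5),
               icu_day = c(10, 12, 13, 17, 20)),
    data.frame(patient_id = sprintf("P%02d", 6:9),
               icu_day = c(30, 34, 35, 40)),
    data.frame(patient_id = "P10", icu_day = 25),
    # twice within the early period (keep first)
    data.frame(patient_id = "P11", icu_day = c(11, 19)),
    # twice within the late period (keep first)
    data.frame(patient_id = "P12", icu_day = c(31, 39)),
    # one in-period + one mid-stay occasion each
    data.frame(patient_id = "P13", icu_day = c(15, 25)),
    data.frame(patient_id = "P14", icu_day = c(16, 26)),
    data.frame(patient_id = "P15", icu_day = c(13, 22)),
    data.frame(patient_id = "P16", icu_day = c(28, 38)),
    data.frame(patient_id = "P17", icu_day = c(27, 36)),
    data.frame(patient_id = "P18", icu_day = c(29, 37)),
    data.frame(patient_id = "P19", icu_day = c(14, 24)),
    # studied three times, spanning both periods (keep last)
    data.frame(patient_id = "P20", icu_day = c(12, 25, 33)))
  occ$value <- seq_len(nrow(occ))
  occ
}

# Random flux configurations inside the model's validity region.
random_valid_truth <- function(n) {
  B <- runif(n, 40, 120)
  NB <- runif(n, -30, 15)
  S <- B + NB
  PF <- runif(n, 2, 5)
  Ca <- runif(n, 40, 90)
  F_MA_max <- pmin(Ca * PF, B * 2.5)
  F_MA <- runif(n, pmax(0.3 * B, NB + 5), F_MA_max)
  Ea <- runif(n, 0.04, 0.12)
  ok <- S > 5 & F_MA - NB > 0 & F_MA < Ca * PF
  data.frame(S = S, B = B, F_MA = F_MA, PF = PF, Ca = Ca, Ea = Ea)[ok, ]
}
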