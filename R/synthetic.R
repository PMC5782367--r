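# Synthetic cohort generator: forward-simulates the steady-state
# compartmental model under the study design (serial occasions every
# 8-12 days between ICU days 10 and 40) with known ground-truth fluxes,
# so that every analysis stage can be checked by parameter recovery.

#' Simulation configuration
#'
#' Ground-truth scenario and noise model for [generate_cohort()]. The
#' defaults encode the study conditions the analysis targets: a constant
#' per-patient protein breakdown rate, a net balance that rises linearly
#' from about -17 nmol/min/100 ml at day 10 through zero at day 35
#' (`nb_slope` * (day - `nb_cross_day`)), unchanging plasma flow and
#' arterial concentrations, a constant 3-methylhistidine efflux, and an
#' amino-acid efflux that decays exponentially over the stay while
#' glutamate is taken up. Flux magnitudes are plausible physiological
#' values chosen as generator defaults.
#'
#' @param n_patients Cohort size (default 20).
#' @param first_day,gap_min,gap_max,censor_day,dropout_prob,max_occasions
#'   Study schedule: first occasion at ICU day 10; subsequent occasions
#'   after a uniform 8-12 day gap, stopping at day 40, with per-occasion
#'   probability `dropout_prob` of leaving the study, and at most
#'   `max_occasions` occasions per patient.
#' @param mu_B,tau_B Population mean and between-patient SD of the
#'   (time-constant) breakdown flux F_M0 (nmol/min/100 ml).
#' @param nb_slope,nb_cross_day Net-balance trend NB(t) =
#'   `nb_slope` * (t - `nb_cross_day`); defaults 0.68 and 35.
#' @param r_transport Ratio F_MA / B of inward transport to breakdown.
#' @param Ca_phe,Ea_phe Arterial phenylalanine concentration (nmol/ml)
#'   and enrichment (TTR).
#' @param ra3_mean,ra3_sd Population mean/SD of the per-patient
#'   (time-constant) 3-MH rate of appearance (nmol/min/100 ml).
#' @param Ca_mh3,Ea_mh3 Arterial 3-MH concentration and enrichment.
#' @param pf_mean,pf_sd Population mean/SD of per-patient plasma flow
#'   (ml/min/100 ml leg), constant over the stay.
#' @param hct_mean,hct_sd Hematocrit distribution.
#' @param aa_release_frac Baseline per-amino-acid efflux as a fraction of
#'   its arterial concentration per unit plasma flow time (day-10 flux =
#'   -`aa_release_frac` * Ca_aa nmol/min/100 ml for released amino acids).
#' @param glu_uptake Baseline glutamate uptake flux (positive,
#'   nmol/min/100 ml).
#' @param aa_decay Exponential decay rate (per day) of the amino-acid
#'   efflux magnitudes after `first_day`.
#' @param cv_conc,cv_enrich,cv_flow Multiplicative lognormal measurement
#'   noise CVs for concentrations, enrichments, and individual occlusion
#'   readings (defaults 3%, 2%, 10%; all noise distributions have mean 1).
#' @param n_readings Occlusion readings per plethysmography phase.
#' @param seed Optional default seed for [generate_cohort()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20,
                       first_day = 10, gap_min = 8, gap_max = 12,
                       censor_day = 40, dropout_prob = 0.5,
                       max_occasions = 3,
                       mu_B = 80, tau_B = 10,
                       nb_slope = 0.68, nb_cross_day = 35,
                       r_transport = 1.0,
                       Ca_phe = 60, Ea_phe = 0.08,
                       ra3_mean = 3.5, ra3_sd = 0.5,
                       Ca_mh3 = 5, Ea_mh3 = 0.05,
                       pf_mean = 3.0, pf_sd = 0.5,
                       hct_mean = 0.30, hct_sd = 0.03,
                       aa_release_frac = 0.12, glu_uptake = 8,
                       aa_decay = 0.03,
                       cv_conc = 0.03, cv_enrich = 0.02, cv_flow = 0.10,
                       n_readings = 10,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (any(c(cfg$cv_conc, cfg$cv_enrich, cfg$cv_flow) < 0)) {
    lt_stop("noise CVs must be >= 0", "lt_config_error")
  }
  if (cfg$nb_slope <= 0) {
    lt_stop("nb_slope must be > 0 (net balance rises toward zero)",
            "lt_config_error")
  }
  if (cfg$gap_min > cfg$gap_max || cfg$gap_min < 1) {
    lt_stop("need 1 <= gap_min <= gap_max", "lt_config_error")
  }
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1) {
    lt_stop("dropout_prob must be in [0, 1]", "lt_config_error")
  }
  structure(cfg, class = "sim_config")
}

# Multiplicative lognormal noise with mean 1 and the given CV.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Noise-free observables implied by a flux configuration
#'
#' The exact inverse of the three-pool algebra: given true synthesis `S`
#' (= F_0M), breakdown `B` (= F_M0), inward transport `F_MA`, plasma
#' flow and the arterial boundary, returns the venous concentration and
#' the venous and intracellular enrichments a steady-state study would
#' observe. Feeding the output to [three_pool()] recovers `(S, B)`
#' exactly; the construction guarantees `Em < Ev < Ea`.
#'
#' @param S,B,F_MA True fluxes (nmol/min/100 ml leg); `B > 0`,
#'   `F_MA <= Ca * PF`, and `F_MA - (S - B) > 0`.
#' @param PF Plasma flow (ml/min/100 ml leg).
#' @param Ca,Ea Arterial concentration (nmol/ml) and enrichment (TTR).
#' @return List: `Cv`, `Ev`, `Em` plus the implied `F_VM`, `F_VA`, `NB`.
#' @export
forward_occasion <- function(S, B, F_MA, PF, Ca, Ea) {
  NB <- S - B
  F_VM <- F_MA - NB
  F_VA <- Ca * PF - F_MA
  if (B <= 0) lt_stop("breakdown B must be > 0", "lt_generation_error")
  if (F_VA < 0) {
    lt_stop("inward transport exceeds arterial delivery (F_MA > Ca*PF)",
            "lt_generation_error")
  }
  if (F_VM <= 0) {
    lt_stop("outward transport F_VM = F_MA - NB must be > 0",
            "lt_generation_error")
  }
  Cv <- Ca - NB / PF
  if (Cv <= 0) lt_stop("implied venous concentration <= 0", "lt_generation_error")
  Em <- Ea * F_MA / (F_MA + B)
  Ev <- (F_VA * Ea + F_VM * Em) / (Cv * PF)
  stopifnot(Em < Ev, Ev < Ea)
  list(Cv = Cv, Ev = Ev, Em = Em, F_VM = F_VM, F_VA = F_VA, NB = NB)
}

#' Noise-free per-amino-acid concentrations for one occasion
#'
#' Arterial concentrations are the reference panel values, constant in
#' time. True fluxes: glutamate is taken up (`+glu_uptake`), every other
#' panel amino acid is released (`-aa_release_frac * Ca_aa`), and both
#' magnitudes decay as `exp(-aa_decay * (day - first_day))`, emulating
#' an efflux that attenuates over the ICU stay. Phenylalanine is the
#' tracer amino acid: its flux is the kinetic net balance `nb`, and its
#' concentrations are taken from the compartmental forward model rather
#' than the decay law.
#'
#' @param config A [sim_config()].
#' @param icu_day Occasion day.
#' @param PF Plasma flow (ml/min/100 ml leg).
#' @param nb True phenylalanine net balance for the occasion.
#' @param Cv_phe True venous phenylalanine concentration.
#' @return List of named vectors `Ca`, `Cv`, `flux` over the panel.
#' @export
generate_aa_panel <- function(config, icu_day, PF, nb, Cv_phe) {
  ref <- aa_reference_conc()
  decay <- exp(-config$aa_decay * (icu_day - config$first_day))
  flux <- -config$aa_release_frac * ref * decay
  flux[["glu"]] <- config$glu_uptake * decay
  Ca <- ref
  Ca[["phe"]] <- config$Ca_phe
  flux[["phe"]] <- nb
  Cv <- Ca - flux / PF
  Cv[["phe"]] <- Cv_phe
  if (any(Cv <= 0)) lt_stop("implied venous amino-acid concentration <= 0",
                            "lt_generation_error")
  list(Ca = Ca, Cv = Cv, flux = flux)
}

rnorm_trunc <- function(n, mean, sd, lower, upper = Inf) {
  v <- rnorm(n, mean, sd)
  pmin(pmax(v, lower), upper)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates the full study: a patient roster, a serial occasion
#' schedule, steady-state arteriovenous samples at minutes 135-150 for
#' both sites, a biopsy enrichment, and pre/post occlusion readings —
#' all derived from the forward compartmental model with multiplicative
#' lognormal measurement noise — together with the ground-truth flux
#' table the analysis should recover. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (required; may also be set in the config).
#' @return List of class `lt_simulation`: `cohort` (an `lt_cohort`),
#'   `truth` (per-occasion true fluxes, wide `flux_<aa>` columns),
#'   `config`.
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed) {
  if (is.null(seed) || is.na(seed)) {
    lt_stop("an explicit seed is required", "lt_config_error")
  }
  set.seed(as.integer(seed))
  cfg <- config
  ids <- sprintf("P%02d", seq_len(cfg$n_patients))

  patients <- data.frame(
    patient_id = ids,
    sex = sample(c("F", "M"), cfg$n_patients, replace = TRUE,
                 prob = c(0.25, 0.75)),
    age = round(rnorm_trunc(cfg$n_patients, 65, 8, 18, 90)),
    bmi = round(rnorm_trunc(cfg$n_patients, 26, 3, 16, 45), 1),
    admission_weight = round(rnorm_trunc(cfg$n_patients, 82, 15, 40, 180), 1),
    diagnosis_class = sample(c("surgical", "medical"), cfg$n_patients,
                             replace = TRUE, prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)

  # Truncation keeps every draw inside the model's validity region
  # (F_MA = r*B must not exceed Ca*PF at the default r and Ca).
  hct <- rnorm_trunc(cfg$n_patients, cfg$hct_mean, cfg$hct_sd, 0.15, 0.50)
  PFi <- rnorm_trunc(cfg$n_patients, cfg$pf_mean, cfg$pf_sd, 2.0)
  Bi <- rnorm_trunc(cfg$n_patients, cfg$mu_B, cfg$tau_B, 30, 115)
  Ra3i <- rnorm_trunc(cfg$n_patients, cfg$ra3_mean, cfg$ra3_sd, 0.5)

  occ_rows <- list(); sam_rows <- list(); bio_rows <- list()
  ple_rows <- list(); tru_rows <- list()

  for (i in seq_len(cfg$n_patients)) {
    days <- as.integer(cfg$first_day)
    while (length(days) < cfg$max_occasions) {
      nxt <- days[length(days)] + sample.int(cfg$gap_max - cfg$gap_min + 1L, 1) +
        as.integer(cfg$gap_min) - 1L
      if (nxt > cfg$censor_day || runif(1) < cfg$dropout_prob) break
      days <- c(days, nxt)
    }
    for (t in days) {
      nb <- cfg$nb_slope * (t - cfg$nb_cross_day)
      S <- Bi[i] + nb
      F_MA <- cfg$r_transport * Bi[i]
      fwd <- forward_occasion(S, Bi[i], F_MA, PFi[i], cfg$Ca_phe, cfg$Ea_phe)
      Cv3 <- cfg$Ca_mh3 + Ra3i[i] / PFi[i]
      Ev3 <- cfg$Ca_mh3 * cfg$Ea_mh3 / Cv3
      aa <- generate_aa_panel(cfg, t, PFi[i], nb, fwd$Cv)

      occ_rows[[length(occ_rows) + 1L]] <- data.frame(
        patient_id = ids[i], icu_day = t, hematocrit = hct[i],
        sofa = sample(3:9, 1), kcal_per_kg_day = round(rnorm(1, 20, 3.2), 1),
        aa_g_per_kg_day = round(rnorm_trunc(1, 1.0, 0.2, 0.2), 2),
        stringsAsFactors = FALSE)

      for (site in SAMPLE_SITES) {
        conc_true <- if (site == "artery") aa$Ca else aa$Cv
        phe_ttr_true <- if (site == "artery") cfg$Ea_phe else fwd$Ev
        mh3_conc_true <- if (site == "artery") cfg$Ca_mh3 else Cv3
        mh3_ttr_true <- if (site == "artery") cfg$Ea_mh3 else Ev3
        for (minute in SAMPLE_MINUTES) {
          row <- data.frame(patient_id = ids[i], icu_day = t,
                            minute = minute, site = site,
                            phe_ttr = phe_ttr_true * rlnorm_cv(1, cfg$cv_enrich),
                            mh3_ttr = mh3_ttr_true * rlnorm_cv(1, cfg$cv_enrich),
                            stringsAsFactors = FALSE)
          noisy <- conc_true * rlnorm_cv(length(conc_true), cfg$cv_conc)
          row[names(conc_true)] <- as.list(noisy)
          row[["mh3"]] <- mh3_conc_true * rlnorm_cv(1, cfg$cv_conc)
          sam_rows[[length(sam_rows) + 1L]] <- row
        }
      }

      bio_rows[[length(bio_rows) + 1L]] <- data.frame(
        patient_id = ids[i], icu_day = t,
        phe_ttr_muscle = fwd$Em * rlnorm_cv(1, cfg$cv_enrich),
        stringsAsFactors = FALSE)

      bf_true <- PFi[i] / (1 - hct[i])
      for (phase in c("pre", "post")) {
        ple_rows[[length(ple_rows) + 1L]] <- data.frame(
          patient_id = ids[i], icu_day = t, phase = phase,
          reading_index = seq_len(cfg$n_readings),
          slope_pct_per_min = bf_true * rlnorm_cv(cfg$n_readings, cfg$cv_flow),
          stringsAsFactors = FALSE)
      }

      tru <- data.frame(patient_id = ids[i], icu_day = t,
                        S = S, B = Bi[i], F_MA = F_MA, F_VM = fwd$F_VM,
                        F_VA = fwd$F_VA, NB = nb, PF = PFi[i],
                        blood_flow = bf_true, hematocrit = hct[i],
                        Ra3 = Ra3i[i],
                        total_aa_flux = sum(aa$flux),
                        stringsAsFactors = FALSE)
      tru[paste0("flux_", names(aa$flux))] <- as.list(aa$flux)
      tru_rows[[length(tru_rows) + 1L]] <- tru
    }
  }

  cohort <- as_cohort(patients,
                      do.call(rbind, occ_rows),
                      do.call(rbind, sam_rows),
                      do.call(rbind, bio_rows),
                      do.call(rbind, ple_rows))
  structure(list(cohort = cohort, truth = do.call(rbind, tru_rows),
                 config = cfg),
            class = "lt_simulation")
}

#' Write a simulation (cohort CSVs, truth table, config echo) to disk
#'
#' @param sim A [generate_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lt_simulation"))
  write_cohort(sim$cohort, dir)
  write_csv_full(sim$truth, file.path(dir, "truth.csv"))
  yaml::write_yaml(unclass(sim$config), file.path(dir, "sim_config.yml"))
  invisible(dir)
}
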