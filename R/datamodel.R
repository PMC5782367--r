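# Domain data model: cohort container, validation, CSV readers/writers.
#
# A cohort is five tables:
#   patients        one row per patient (descriptive metadata)
#   occasions       one row per patient x study day (hematocrit, intake)
#   samples         one row per occasion x minute x site; wide amino-acid
#                   concentration columns (lower-case 3-letter codes, plus
#                   "mh3" for 3-methylhistidine) and tracer enrichments
#   biopsies        one row per occasion with biopsy free-phe enrichment
#   plethysmography one row per occasion x phase x reading
#
# Concentrations are umol/L (== nmol/ml); enrichments are TTR.

SAMPLE_MINUTES <- c(135L, 140L, 145L, 150L)
SAMPLE_SITES <- c("artery", "vein")

lt_stop <- function(msg, class) {
  stop(structure(class = c(class, "lt_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

occasion_key <- function(patient_id, icu_day) paste(patient_id, icu_day, sep = "@")

conc_columns <- function(samples) {
  meta <- c("patient_id", "icu_day", "minute", "site", "phe_ttr", "mh3_ttr")
  setdiff(names(samples), meta)
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    lt_stop(sprintf("table '%s' is missing mandatory column(s): %s",
                    table, paste(missing, collapse = ", ")),
            "lt_schema_error")
  }
}

#' Assemble and validate a cohort from its component tables
#'
#' Checks every structural invariant of the data model: identifier
#' uniqueness and referential integrity, the allowed sampling minutes
#' (135, 140, 145, 150) and sites, hematocrit strictly inside (0, 1),
#' non-negative concentrations, enrichments in `[0, 1)`, positive
#' occlusion slopes, and unique plethysmography reading indices.
#'
#' @param patients,occasions,samples,biopsies,plethysmography Data frames;
#'   see the column dictionary in the package vignette.
#' @return A validated list of class `lt_cohort`.
#' @export
as_cohort <- function(patients, occasions, samples, biopsies, plethysmography) {
  require_columns(patients, c("patient_id", "sex", "age", "bmi",
                              "admission_weight", "diagnosis_class"),
                  "patients")
  require_columns(occasions, c("patient_id", "icu_day", "hematocrit"),
                  "occasions")
  require_columns(samples, c("patient_id", "icu_day", "minute", "site",
                             "phe_ttr", "mh3_ttr", "phe", "mh3"),
                  "samples")
  require_columns(biopsies, c("patient_id", "icu_day", "phe_ttr_muscle"),
                  "biopsies")
  require_columns(plethysmography, c("patient_id", "icu_day", "phase",
                                     "reading_index", "slope_pct_per_min"),
                  "plethysmography")

  if (anyDuplicated(patients$patient_id)) {
    lt_stop("duplicated patient_id in patients table", "lt_integrity_error")
  }
  if (any(!is.na(patients$age) & patients$age <= 0)) {
    lt_stop("age must be > 0", "lt_validation_error")
  }
  if (any(!is.na(patients$bmi) & patients$bmi <= 0)) {
    lt_stop("bmi must be > 0", "lt_validation_error")
  }
  bad_dx <- setdiff(unique(patients$diagnosis_class), c("medical", "surgical", NA))
  if (length(bad_dx)) {
    lt_stop(paste0("diagnosis_class must be one of {medical, surgical}; got: ",
                   paste(bad_dx, collapse = ", ")), "lt_validation_error")
  }

  if (any(occasions$icu_day < 1 | occasions$icu_day != round(occasions$icu_day))) {
    lt_stop("icu_day must be an integer >= 1", "lt_validation_error")
  }
  if (any(occasions$hematocrit <= 0 | occasions$hematocrit >= 1)) {
    lt_stop("hematocrit must lie strictly inside (0, 1)", "lt_validation_error")
  }
  okey <- occasion_key(occasions$patient_id, occasions$icu_day)
  if (anyDuplicated(okey)) {
    lt_stop("duplicated (patient_id, icu_day) in occasions table",
            "lt_integrity_error")
  }
  orphan <- setdiff(unique(occasions$patient_id), patients$patient_id)
  if (length(orphan)) {
    lt_stop(paste0("occasions reference unknown patient_id: ",
                   paste(orphan, collapse = ", ")), "lt_integrity_error")
  }

  if (!all(samples$minute %in% SAMPLE_MINUTES)) {
    bad <- setdiff(unique(samples$minute), SAMPLE_MINUTES)
    lt_stop(sprintf("sample minute(s) %s outside the allowed set {%s}",
                    paste(bad, collapse = ", "),
                    paste(SAMPLE_MINUTES, collapse = ",")),
            "lt_validation_error")
  }
  if (!all(samples$site %in% SAMPLE_SITES)) {
    lt_stop("sample site must be 'artery' or 'vein'", "lt_validation_error")
  }
  skey <- paste(occasion_key(samples$patient_id, samples$icu_day),
                samples$minute, samples$site)
  if (anyDuplicated(skey)) {
    lt_stop("duplicated (occasion, minute, site) in samples table",
            "lt_integrity_error")
  }
  if (length(setdiff(occasion_key(samples$patient_id, samples$icu_day), okey))) {
    lt_stop("samples reference an occasion absent from occasions table",
            "lt_integrity_error")
  }
  cc <- conc_columns(samples)
  for (col in cc) {
    v <- samples[[col]]
    if (any(!is.na(v) & v < 0)) {
      lt_stop(paste0("negative concentration in samples column '", col, "'"),
              "lt_validation_error")
    }
  }
  for (col in c("phe_ttr", "mh3_ttr")) {
    v <- samples[[col]]
    if (any(!is.na(v) & (v < 0 | v >= 1))) {
      lt_stop(paste0("enrichment '", col, "' must lie in [0, 1)"),
              "lt_validation_error")
    }
  }

  if (any(biopsies$phe_ttr_muscle < 0 | biopsies$phe_ttr_muscle >= 1)) {
    lt_stop("phe_ttr_muscle must lie in [0, 1)", "lt_validation_error")
  }
  bkey <- occasion_key(biopsies$patient_id, biopsies$icu_day)
  if (anyDuplicated(bkey)) {
    lt_stop("duplicated biopsy for an occasion", "lt_integrity_error")
  }
  if (length(setdiff(bkey, okey))) {
    lt_stop("biopsies reference an occasion absent from occasions table",
            "lt_integrity_error")
  }

  if (!all(plethysmography$phase %in% c("pre", "post"))) {
    lt_stop("plethysmography phase must be 'pre' or 'post'",
            "lt_validation_error")
  }
  if (any(!is.finite(plethysmography$slope_pct_per_min) |
          plethysmography$slope_pct_per_min <= 0)) {
    lt_stop("occlusion slopes must be finite and > 0", "lt_validation_error")
  }
  pkey <- paste(occasion_key(plethysmography$patient_id, plethysmography$icu_day),
                plethysmography$phase, plethysmography$reading_index)
  if (anyDuplicated(pkey)) {
    lt_stop("duplicated plethysmography reading index within a phase",
            "lt_integrity_error")
  }
  if (length(setdiff(occasion_key(plethysmography$patient_id,
                                  plethysmography$icu_day), okey))) {
    lt_stop("plethysmography references an occasion absent from occasions table",
            "lt_integrity_error")
  }

  structure(list(patients = patients, occasions = occasions,
                 samples = samples, biopsies = biopsies,
                 plethysmography = plethysmography),
            class = "lt_cohort")
}

#' @export
print.lt_cohort <- function(x, ...) {
  cat("<lt_cohort>", nrow(x$patients), "patients,",
      nrow(x$occasions), "occasions,", nrow(x$samples), "timed samples,",
      nrow(x$biopsies), "biopsies\n")
  invisible(x)
}

cohort_files <- c(patients = "patients.csv", occasions = "occasions.csv",
                  samples = "samples.csv", biopsies = "biopsies.csv",
                  plethysmography = "plethysmography.csv")

#' Load a cohort from a directory of CSV files
#'
#' Reads `patients.csv`, `occasions.csv`, `samples.csv`, `biopsies.csv`
#' and `plethysmography.csv` from `dir` and validates them with
#' [as_cohort()]. Concentration columns are umol/L, which equals nmol/ml,
#' so no unit conversion is applied.
#'
#' @param dir Directory containing the five cohort CSV files.
#' @param config An [lt_config()] object (recorded; validation thresholds).
#' @return An `lt_cohort`.
#' @export
load_cohort <- function(dir, config = lt_config()) {
  paths <- file.path(dir, cohort_files)
  names(paths) <- names(cohort_files)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    lt_stop(paste0("cohort file(s) not found: ",
                   paste(missing, collapse = ", ")), "lt_schema_error")
  }
  tabs <- lapply(paths, read.csv, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(tabs$patients, tabs$occasions, tabs$samples, tabs$biopsies,
            tabs$plethysmography)
}

# Full-precision CSV writer: numeric columns are serialized with %.17g so
# that a write/read round trip is exact for doubles.
write_csv_full <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write a cohort to a directory of CSV files
#'
#' Inverse of [load_cohort()]. Doubles are written with 17 significant
#' digits, so `load_cohort(write_cohort(x))` reproduces every numeric
#' field exactly.
#'
#' @param cohort An `lt_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort_files)) {
    write_csv_full(cohort[[nm]], file.path(dir, cohort_files[[nm]]))
  }
  invisible(dir)
}

#' Average an occasion's timed samples into the kinetic-model inputs
#'
#' Computes the arithmetic mean over the sampling timepoints, separately
#' per site, of every concentration and enrichment; concentrations and
#' enrichments are averaged individually, never their products, because
#' the steady-state models evaluate fluxes once per occasion. The biopsy
#' enrichment (Em) and plasma flow (PF) are attached unchanged.
#'
#' @param samples Rows of the samples table for one occasion (both sites).
#' @param biopsy Optional one-row biopsy data frame for the occasion;
#'   `NULL` marks the intracellular enrichment unavailable (the two-pool
#'   model still applies; the three-pool model will be `NA`).
#' @param flow A [FlowResult][occasion_flow()] or a plasma-flow scalar
#'   (ml/min/100 ml leg).
#' @param config An [lt_config()]; `qc$min_timepoints` below 4 downgrades
#'   an incomplete occasion from an error to a warning.
#' @return An object of class `occasion_averages` with fields `Ca`, `Cv`,
#'   `Ea`, `Ev`, `Em`, `Ca3`, `Cv3`, `Ea3`, `Ev3`, `PF`, and named
#'   per-amino-acid vectors `aa_arterial`, `aa_venous`.
#' @export
average_occasion <- function(samples, biopsy = NULL, flow = NULL,
                             config = lt_config()) {
  min_tp <- config$qc$min_timepoints
  art <- samples[samples$site == "artery", , drop = FALSE]
  ven <- samples[samples$site == "vein", , drop = FALSE]
  for (s in list(artery = art, vein = ven)) {
    n <- nrow(s)
    if (n < 4) {
      msg <- sprintf("occasion has %d timepoint(s) for a site; 4 expected", n)
      if (n >= max(2, min_tp)) warning(msg, call. = FALSE)
      else lt_stop(msg, "lt_incomplete_occasion_error")
    }
  }
  pf <- if (inherits(flow, "flow_result")) flow$plasma_flow
        else if (is.numeric(flow) && length(flow) == 1) flow
        else NA_real_
  cc <- conc_columns(samples)
  av <- structure(list(
    Ca = mean(art$phe), Cv = mean(ven$phe),
    Ea = mean(art$phe_ttr), Ev = mean(ven$phe_ttr),
    Em = if (is.null(biopsy)) NA_real_ else biopsy$phe_ttr_muscle[[1]],
    Ca3 = mean(art$mh3), Cv3 = mean(ven$mh3),
    Ea3 = mean(art$mh3_ttr), Ev3 = mean(ven$mh3_ttr),
    PF = pf,
    aa_arterial = vapply(art[cc], mean, numeric(1)),
    aa_venous = vapply(ven[cc], mean, numeric(1))
  ), class = "occasion_averages")
  av
}

#' Within-occasion steady-state quality control
#'
#' The kinetic models assume metabolic and isotopic steady state over the
#' sampling window. This check computes, per site and analyte, the
#' coefficient of variation across timepoints and flags analytes whose CV
#' exceeds the threshold. A zero mean makes the CV undefined; such series
#' are flagged as degenerate.
#'
#' @param samples Rows of the samples table for one occasion.
#' @param cv_threshold Flag level for CV (default 0.15, i.e. 15%).
#' @return Data frame with columns `site`, `analyte`, `mean`, `sd`, `cv`,
#'   `flag`, `degenerate`.
#' @export
steady_state_qc <- function(samples, cv_threshold = 0.15) {
  analytes <- c(conc_columns(samples), "phe_ttr", "mh3_ttr")
  rows <- list()
  for (site in unique(samples$site)) {
    sub <- samples[samples$site == site, , drop = FALSE]
    if (nrow(sub) < 2) {
      lt_stop("steady-state QC needs at least 2 timepoints per site",
              "lt_incomplete_occasion_error")
    }
    for (a in analytes) {
      v <- sub[[a]]
      m <- mean(v)
      s <- sd(v)
      degenerate <- m == 0
      cv <- if (degenerate) NA_real_ else s / m
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, analyte = a, mean = m, sd = s, cv = cv,
        flag = degenerate || (is.finite(cv) && cv > cv_threshold),
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
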