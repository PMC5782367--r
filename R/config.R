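#' Analysis configuration
#'
#' Nested configuration shared by all pipeline stages. Call with no
#' arguments for the defaults; pass named lists per section to override
#' individual entries, or read overrides from a YAML file with
#' [read_config()].
#'
#' Sections:
#' \describe{
#'   \item{units}{`conc` (`"umol_per_L"`, identical to nmol/ml) and
#'     `enrichment` (`"ttr"`), recorded for provenance.}
#'   \item{qc}{`cv_threshold` — coefficient-of-variation flag level for the
#'     isotopic/metabolic steady-state check (default 0.15);
#'     `min_timepoints` — timepoints required per site before an occasion is
#'     averaged (default 4; set to 2 to warn and use what is available).}
#'   \item{kinetics}{`ordering_tolerance` — absolute slack on the enrichment
#'     ordering Em < Ev < Ea; violations within it are clamped, larger ones
#'     error (default 1e-9). `min_readings` — plethysmography readings
#'     required per phase (default 5). `trim_readings` — optional
#'     median-based trimming of occlusion readings (default FALSE).}
#'   \item{stats}{`df_method` — reference distribution for the mixed-model
#'     slope test, `"within"` (nlme within-group t, default) or
#'     `"normal"` (large-sample Wald z);
#'     `mw_exact_max_n` — largest combined sample size for exact
#'     Mann-Whitney enumeration (default 12); `holm` — apply Holm correction
#'     across outcomes (default FALSE, matching an unadjusted multi-outcome
#'     analysis).}
#'   \item{simulate}{see [sim_config()].}
#' }
#'
#' @param units,qc,kinetics,stats,simulate Named lists of overrides.
#' @return A nested list of class `lt_config`.
#' @export
lt_config <- function(units = list(), qc = list(), kinetics = list(),
                      stats = list(), simulate = list()) {
  cfg <- list(
    units = list(conc = "umol_per_L", enrichment = "ttr"),
    qc = list(cv_threshold = 0.15, min_timepoints = 4),
    kinetics = list(ordering_tolerance = 1e-9, min_readings = 5,
                    trim_readings = FALSE),
    stats = list(df_method = "within", mw_exact_max_n = 12, holm = FALSE),
    simulate = unclass(sim_config())
  )
  over <- list(units = units, qc = qc, kinetics = kinetics, stats = stats,
               simulate = simulate)
  for (sec in names(over)) {
    unknown <- setdiff(names(over[[sec]]), names(cfg[[sec]]))
    if (length(unknown)) {
      stop("unknown config entr", if (length(unknown) > 1) "ies" else "y",
           " in section '", sec, "': ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[[sec]] <- modifyList(cfg[[sec]], over[[sec]])
  }
  structure(cfg, class = "lt_config")
}

#' Read configuration overrides from a YAML file
#'
#' The file may contain any subset of the sections of [lt_config()];
#' entries present override the defaults, everything else keeps them.
#'
#' @param path Path to a YAML file.
#' @return An `lt_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("units", "qc", "kinetics", "stats", "simulate")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(lt_config, y[intersect(names(y), known)])
}
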