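# Per-amino-acid net fluxes across the leg: for amino acids without a
# tracer, net balance combined with plasma flow is the measure of exchange.

#' Per-amino-acid and total net fluxes across the leg
#'
#' Flux of each panel amino acid is `(Ca - Cv) * PF`; negative = net
#' release from muscle into venous blood, positive = net uptake. The
#' total is the sum over the panel. 3-methylhistidine (`"mh3"`), when
#' present in the averages, is never part of the panel total.
#'
#' @param av An [average_occasion()] result (uses `aa_arterial`,
#'   `aa_venous`, `PF`), or any list with those fields.
#' @param panel Character vector of amino-acid codes to include
#'   (default [aa_panel_default()]). Panel members missing from the data
#'   are dropped from the totals with a warning.
#' @return Object of class `aa_flux_result`: named vectors `flux` and
#'   `arterial_conc` over the panel, scalars `total_flux` and
#'   `total_arterial`, and `panel_used`.
#' @export
aa_fluxes <- function(av, panel = aa_panel_default()) {
  if (length(panel) == 0) {
    lt_stop("amino-acid panel is empty", "lt_config_error")
  }
  panel <- setdiff(panel, "mh3")
  have <- intersect(panel, intersect(names(av$aa_arterial), names(av$aa_venous)))
  missing <- setdiff(panel, have)
  if (length(missing)) {
    warning("panel amino acid(s) missing from data, excluded from totals: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(have) == 0) {
    lt_stop("no panel amino acid present in the data", "lt_config_error")
  }
  Ca <- av$aa_arterial[have]
  Cv <- av$aa_venous[have]
  flux <- net_balance(Ca, Cv, av$PF)
  structure(list(flux = flux,
                 total_flux = sum(flux),
                 arterial_conc = Ca,
                 total_arterial = sum(Ca),
                 panel_used = have),
            class = "aa_flux_result")
}

#' @export
print.aa_flux_result <- function(x, ...) {
  cat(sprintf("<aa_flux> total flux %.1f nmol/min/100 ml over %d amino acids (total arterial %.0f umol/L)\n",
              x$total_flux, length(x$panel_used), x$total_arterial))
  invisible(x)
}
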