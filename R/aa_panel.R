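#' Amino-acid panel
#'
#' The default panel is the 20 proteinogenic amino acids, identified by
#' lower-case three-letter codes. 3-methylhistidine carries the code
#' `"mh3"`; it is measured and reported but excluded from panel totals
#' (it is a post-translational marker, not a free proteinogenic pool).
#'
#' @return Character vector of panel codes.
#' @export
aa_panel_default <- function() {
  c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his", "ile",
    "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp", "tyr", "val")
}

# Typical fasting-state arterial plasma concentrations (umol/L == nmol/ml),
# used as generator defaults for the synthetic cohort.
aa_reference_conc <- function() {
  c(ala = 330, arg = 80, asn = 45, asp = 10, cys = 40, gln = 550, glu = 60,
    gly = 230, his = 80, ile = 65, leu = 130, lys = 180, met = 25, phe = 60,
    pro = 180, ser = 110, thr = 130, trp = 50, tyr = 60, val = 230)
}

#' Convert between TTR and mole percent excess
#'
#' Enrichment in this package is the tracer-to-tracee ratio (TTR). Mole
#' percent excess, the other scale in common use, is MPE = 100 * TTR /
#' (1 + TTR). These helpers convert between the two.
#'
#' @param ttr Tracer-to-tracee ratio, in `[0, 1)`.
#' @param mpe Mole percent excess, percent.
#' @return The converted enrichment.
#' @export
ttr_to_mpe <- function(ttr) 100 * ttr / (1 + ttr)

#' @rdname ttr_to_mpe
#' @export
mpe_to_ttr <- function(mpe) {
  f <- mpe / 100
  f / (1 - f)
}
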