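# Arteriovenous phenylalanine kinetics.
#
# Phenylalanine is neither synthesized nor degraded in muscle, so its
# disappearance into the leg reflects incorporation into protein
# (synthesis) and its appearance reflects proteolysis (breakdown).
#
# Two-pool model (artery/vein only): dilution of the arterial tracer
# across the leg gives
#   NB = (Ca - Cv) * PF
#   Rd = PF * (Ca*Ea - Cv*Ev) / Ea      (disappearance ~ synthesis)
#   Ra = Rd - NB                        (appearance  ~ breakdown)
# Intracellular recycling of breakdown-derived phenylalanine into new
# protein is invisible to this model.
#
# Three-pool model (artery / muscle free pool / vein): the biopsy
# enrichment Em resolves transmembrane transport and the "real"
# intracellular rates. At steady state:
#   F_VM = PF * Cv * (Ea - Ev) / (Ea - Em)   muscle -> vein transport
#   F_MA = NB + F_VM                         artery -> muscle transport
#   F_VA = Ca * PF - F_MA                    arteriovenous shunt
#   F_M0 = F_MA * (Ea - Em) / Em             proteolysis (breakdown)
#   F_0M = F_M0 + NB                         synthesis
# All in nmol/min per 100 ml leg; negative NB = net release from muscle.

#' Net balance of a substance across the leg
#'
#' @param Ca,Cv Arterial and venous plasma concentrations (nmol/ml).
#' @param PF Plasma flow (ml/min/100 ml leg), > 0.
#' @return Net balance (nmol/min/100 ml leg); negative = net release.
#' @export
net_balance <- function(Ca, Cv, PF) {
  if (any(PF <= 0)) lt_stop("plasma flow must be > 0", "lt_domain_error")
  if (any(Ca < 0 | Cv < 0)) {
    lt_stop("concentrations must be >= 0", "lt_domain_error")
  }
  (Ca - Cv) * PF
}

# Shared two-pool algebra for any tracer/tracee pair.
two_pool_core <- function(Ca, Cv, Ea, Ev, PF, label) {
  if (Ea <= 0) {
    lt_stop(paste0("arterial ", label, " enrichment is zero: two-pool model degenerate"),
            "lt_degenerate_enrichment_error")
  }
  inverted <- Ev > Ea
  if (inverted) {
    warning(sprintf("venous %s enrichment exceeds arterial (Ev = %g > Ea = %g): inverted gradient, results flagged",
                    label, Ev, Ea), call. = FALSE)
  }
  NB <- net_balance(Ca, Cv, PF)
  Rd <- PF * (Ca * Ea - Cv * Ev) / Ea
  list(NB = NB, Rd = Rd, Ra = Rd - NB, inverted_gradient = inverted)
}

#' Two-pool phenylalanine model
#'
#' @param av An [average_occasion()] result (or any list with `Ca`, `Cv`,
#'   `Ea`, `Ev`, `PF`).
#' @return Object of class `two_pool_result`: `NB`, `Rd` (synthesis
#'   estimate), `Ra` (breakdown estimate), `inverted_gradient` flag.
#'   The identity `NB = Rd - Ra` holds exactly.
#' @export
two_pool <- function(av) {
  res <- two_pool_core(av$Ca, av$Cv, av$Ea, av$Ev, av$PF, "phe")
  structure(res, class = "two_pool_result")
}

#' Three-pool phenylalanine model
#'
#' Requires the muscle biopsy free-phenylalanine enrichment and the
#' strict ordering `Em < Ev < Ea` (arterial tracer is diluted first by
#' the venous admixture, further by intracellular proteolysis).
#' Ordering violations within `tolerance` are clamped — measurement noise
#' can graze the boundary — while larger violations raise an error naming
#' the violated inequality.
#'
#' @param av An [average_occasion()] result with `Em` available.
#' @param tolerance Absolute clamp for ordering violations (default 1e-9).
#' @return Object of class `three_pool_result` with transport fluxes
#'   `F_MA` (inward), `F_VM` (outward), `F_VA` (shunt), turnover fluxes
#'   `F_M0` (breakdown), `F_0M` (synthesis), `NB`, and a
#'   `shunt_negative` flag. Identities `F_0M - F_M0 = NB`,
#'   `F_MA + F_M0 = F_VM + F_0M` and `F_VA + F_MA = Ca * PF` hold to
#'   machine precision.
#' @export
three_pool <- function(av, tolerance = 1e-9) {
  Ca <- av$Ca; Cv <- av$Cv; Ea <- av$Ea; Ev <- av$Ev; Em <- av$Em; PF <- av$PF
  if (is.null(Em) || is.na(Em)) {
    lt_stop("muscle biopsy enrichment unavailable: three-pool model not applicable",
            "lt_degenerate_enrichment_error")
  }
  if (Em <= 0) {
    lt_stop("muscle enrichment must be > 0 for the three-pool model",
            "lt_degenerate_enrichment_error")
  }
  if (PF <= 0) lt_stop("plasma flow must be > 0", "lt_domain_error")
  if (Ev > Ea) {
    if (Ev - Ea > tolerance) {
      lt_stop(sprintf("enrichment ordering violated: Ev (%g) > Ea (%g)", Ev, Ea),
              "lt_ordering_error")
    }
    Ev <- Ea
  }
  if (Em > Ev) {
    if (Em - Ev > tolerance) {
      lt_stop(sprintf("enrichment ordering violated: Em (%g) > Ev (%g)", Em, Ev),
              "lt_ordering_error")
    }
    Em <- Ev
  }
  NB <- net_balance(Ca, Cv, PF)
  F_VM <- PF * Cv * (Ea - Ev) / (Ea - Em)
  F_MA <- NB + F_VM
  F_VA <- Ca * PF - F_MA
  F_M0 <- F_MA * (Ea - Em) / Em
  F_0M <- F_M0 + NB
  structure(list(F_MA = F_MA, F_VM = F_VM, F_VA = F_VA,
                 F_M0 = F_M0, F_0M = F_0M, NB = NB,
                 shunt_negative = F_VA < 0),
            class = "three_pool_result")
}

#' @export
print.two_pool_result <- function(x, ...) {
  cat(sprintf("<two_pool> NB %.2f, Rd %.2f, Ra %.2f nmol/min/100 ml\n",
              x$NB, x$Rd, x$Ra))
  invisible(x)
}

#' @export
print.three_pool_result <- function(x, ...) {
  cat(sprintf("<three_pool> NB %.2f | synthesis F_0M %.2f, breakdown F_M0 %.2f | transport F_MA %.2f, F_VM %.2f, shunt F_VA %.2f\n",
              x$NB, x$F_0M, x$F_M0, x$F_MA, x$F_VM, x$F_VA))
  invisible(x)
}

#' Intracellular recycling invisible to the two-pool model
#'
#' The two-pool model cannot see phenylalanine released by proteolysis
#' and re-incorporated into protein without leaving the leg. The gap
#' between the three-pool and two-pool rates quantifies it; its two
#' components are identical because both models share the same net
#' balance.
#'
#' @param two A `two_pool_result`.
#' @param three A `three_pool_result` from the same occasion.
#' @return Named vector `c(synthesis_gap = F_0M - Rd,
#'   breakdown_gap = F_M0 - Ra)`, both non-negative under valid
#'   enrichment ordering.
#' @export
recycling_gap <- function(two, three) {
  stopifnot(inherits(two, "two_pool_result"),
            inherits(three, "three_pool_result"))
  c(synthesis_gap = three$F_0M - two$Rd,
    breakdown_gap = three$F_M0 - two$Ra)
}
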