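# 3-methylhistidine (3-MH) kinetics. 3-MH arises only by post-translational
# methylation of histidine residues in actin and myosin; humans can neither
# degrade nor re-use it, so its rate of appearance across the leg indexes
# contractile-protein breakdown specifically. The no-reuse biology predicts
# Rd3 ~ 0; Rd3 is reported rather than forced to zero so that deviations
# act as a built-in quality-control signal.

#' Two-pool 3-methylhistidine model
#'
#' Identical algebra to the phenylalanine [two_pool()] model applied to
#' the 3-MH concentrations and enrichments.
#'
#' @param av An [average_occasion()] result (fields `Ca3`, `Cv3`, `Ea3`,
#'   `Ev3`, `PF`).
#' @return Object of class `mh3_result`: `NB3`, `Rd3`, `Ra3`
#'   (nmol/min/100 ml leg), `inverted_gradient` flag; `NB3 = Rd3 - Ra3`
#'   exactly. `Ra3` is the contractile-protein breakdown index.
#' @export
mh3_two_pool <- function(av) {
  res <- two_pool_core(av$Ca3, av$Cv3, av$Ea3, av$Ev3, av$PF, "3-MH")
  structure(list(NB3 = res$NB, Rd3 = res$Rd, Ra3 = res$Ra,
                 inverted_gradient = res$inverted_gradient),
            class = "mh3_result")
}

#' @export
print.mh3_result <- function(x, ...) {
  cat(sprintf("<mh3_result> NB3 %.3f, Rd3 %.3f, Ra3 %.3f nmol/min/100 ml\n",
              x$NB3, x$Rd3, x$Ra3))
  invisible(x)
}
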