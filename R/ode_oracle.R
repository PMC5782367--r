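# Dynamical cross-check of the algebraic flux estimators.
#
# The three-pool equations are steady-state mass balances. This module
# builds the corresponding dynamical system — a fixed arterial boundary,
# a muscle free pool and a venous mixing pool, with tracee and tracer
# amounts integrated explicitly — runs it to steady state numerically,
# and returns the observables a study would measure. Feeding those to
# two_pool()/three_pool() must reproduce the imposed fluxes; the
# integration route shares no algebra with the estimators.

#' Steady-state observables of the three-compartment tracer system
#'
#' Imposes a flux configuration (synthesis `S` = F_0M, breakdown `B` =
#' F_M0, inward transport `F_MA`, plasma flow `PF`, arterial boundary
#' `Ca`, `Ea`) on the compartmental ODE system and integrates tracee and
#' tracer amounts in the muscle free pool and the venous pool until
#' stationary. Outflows leave each pool in proportion to its content;
#' proteolysis delivers unlabeled phenylalanine only.
#'
#' @param S Protein synthesis flux F_0M (nmol/min/100 ml leg).
#' @param B Protein breakdown flux F_M0.
#' @param F_MA Inward transmembrane transport; must not exceed `Ca * PF`,
#'   and `F_VM = F_MA - (S - B)` must be positive.
#' @param PF Plasma flow (ml/min/100 ml leg).
#' @param Ca,Ea Arterial phenylalanine concentration (nmol/ml) and
#'   enrichment (TTR), held fixed.
#' @param V_M,V_V Distribution volumes of the muscle free pool and venous
#'   pool (ml per 100 ml leg); arbitrary positive values that set the
#'   relaxation times but not the steady state.
#' @param C_M Assumed steady-state muscle free concentration (nmol/ml),
#'   fixing the first-order outflow constants; does not affect the
#'   steady-state enrichments.
#' @param t_end Integration horizon (min).
#' @param rtol,atol Integrator tolerances (deSolve::lsoda).
#' @return List with observables `Cv`, `Ev`, `Em` (plus `Ca`, `Ea`, `PF`)
#'   and the implied fluxes for reference.
#' @export
ode_steady_observables <- function(S, B, F_MA, PF, Ca, Ea,
                                   V_M = 5, V_V = 2, C_M = 100,
                                   t_end = 2000, rtol = 1e-10, atol = 1e-10) {
  NB <- S - B
  F_VM <- F_MA - NB
  F_VA <- Ca * PF - F_MA
  if (B <= 0 || F_VM <= 0 || F_VA < 0 || PF <= 0) {
    lt_stop("invalid flux configuration: need B > 0, F_VM > 0, F_MA <= Ca*PF, PF > 0",
            "lt_domain_error")
  }
  Q_M_ss <- C_M * V_M
  k_VM <- F_VM / Q_M_ss
  k_0M <- S / Q_M_ss

  deriv <- function(t, y, parms) {
    Q_M <- y[1]; q_M <- y[2]; Q_V <- y[3]; q_V <- y[4]
    list(c(
      F_MA + B - (k_VM + k_0M) * Q_M,
      F_MA * Ea - (k_VM + k_0M) * q_M,
      F_VA + k_VM * Q_M - PF * Q_V / V_V,
      F_VA * Ea + k_VM * q_M - PF * q_V / V_V
    ))
  }
  y0 <- c(Q_M = 0.5 * Q_M_ss, q_M = 0, Q_V = 0.5 * Ca * V_V, q_V = 0)
  sol <- deSolve::lsoda(y0, times = c(0, t_end), func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  yT <- sol[nrow(sol), -1]
  list(Ca = Ca, Ea = Ea, PF = PF,
       Cv = unname(yT["Q_V"]) / V_V,
       Ev = unname(yT["q_V"] / yT["Q_V"]),
       Em = unname(yT["q_M"] / yT["Q_M"]),
       imposed = list(S = S, B = B, F_MA = F_MA, F_VM = F_VM, F_VA = F_VA,
                      NB = NB))
}
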