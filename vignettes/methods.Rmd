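---
title: "Arteriovenous tracer kinetics of leg muscle protein turnover: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arteriovenous tracer kinetics of leg muscle protein turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(legturnover)
```

## The measurement problem

Skeletal-muscle protein mass is the balance of two large, opposing fluxes:
protein synthesis and protein breakdown. Neither is observable directly in
a living patient. What *can* be measured across a limb during a
primed-continuous infusion of a stable-isotope-labelled amino acid is:

* arterial and deep-venous plasma concentrations of the tracee,
* the tracer enrichment (tracer-to-tracee ratio, TTR) at both sites,
* the free tracee's enrichment inside the muscle (one biopsy),
* limb blood flow (venous-occlusion plethysmography), and the
  hematocrit that converts it to plasma flow.

Phenylalanine is the tracer of choice for mixed muscle protein because
muscle neither synthesizes nor degrades it: every phenylalanine molecule
that disappears across the leg went into protein, and every one that
appears came out of protein. `legturnover` implements the steady-state
balance models that turn those measurements into synthesis, breakdown and
net-balance fluxes, the companion 3-methylhistidine and per-amino-acid
balances, and the longitudinal statistics used to follow a cohort of
long-stay ICU patients across their stay. All fluxes are expressed per
100 ml of leg volume; a **negative** net balance means net release from
muscle.

## The two-pool model

With `Ca`, `Cv` the arterial/venous tracee concentrations (nmol/ml),
`Ea`, `Ev` the TTRs, and `PF` the plasma flow (ml/min/100 ml leg):

$$\mathrm{NB} = (C_a - C_v)\,\mathrm{PF}, \qquad
R_d = \mathrm{PF}\,\frac{C_a E_a - C_v E_v}{E_a}, \qquad
R_a = R_d - \mathrm{NB}.$$

$R_d$ (rate of disappearance) estimates synthesis and $R_a$ (rate of
appearance) breakdown. The model's blind spot is intracellular
recycling: tracee released by proteolysis and re-incorporated into
protein without ever leaving the leg is invisible, so both rates are
lower bounds.

## The three-pool model

Adding the muscle free pool's enrichment `Em` (biopsy) resolves
transmembrane transport and the "real" intracellular rates. Under
steady-state mass balance with the strict ordering $E_m < E_v < E_a$:

$$F_{V,M} = \mathrm{PF}\,C_v\,\frac{E_a - E_v}{E_a - E_m},\qquad
F_{M,A} = \mathrm{NB} + F_{V,M},\qquad
F_{V,A} = C_a\,\mathrm{PF} - F_{M,A},$$
$$F_{M,0} = F_{M,A}\,\frac{E_a - E_m}{E_m} \;(\text{breakdown}),\qquad
F_{0,M} = F_{M,0} + \mathrm{NB} \;(\text{synthesis}).$$

Three identities hold to machine precision on any input and are asserted
by the test suite: $F_{0,M}-F_{M,0}=\mathrm{NB}$,
$F_{M,A}+F_{M,0}=F_{V,M}+F_{0,M}$, and $F_{V,A}+F_{M,A}=C_a\,\mathrm{PF}$.
The recycling invisible to the two-pool model is
`recycling_gap()` $= (F_{0,M}-R_d, F_{M,0}-R_a)$; its two components are
identical because both models share the same net balance, and both are
non-negative whenever the enrichment ordering holds.

Because these are steady-state *algebraic* equations, the package also
ships a genuinely independent check: `ode_steady_observables()`
integrates the corresponding three-compartment tracer/tracee dynamical
system (fixed arterial boundary, muscle free pool with first-order
outflows, venous mixing pool) with `deSolve` until stationary, and the
test suite verifies that feeding the integrated observables back through
`two_pool()`/`three_pool()` reproduces the imposed fluxes to better than
one part in $10^6$. This guards the algebra against sign and
transcription drift in a way that re-deriving it cannot.

## 3-methylhistidine and the amino-acid panel

3-methylhistidine arises only by post-translational methylation of
histidine in actin and myosin, and humans can neither degrade nor
re-use it, so its rate of appearance across the leg indexes
contractile-protein breakdown specifically. `mh3_two_pool()` applies the
identical two-pool algebra to the labelled 3-MH measurements. The
no-reuse biology predicts $R_{d,3}\approx 0$; the estimate is reported
rather than clamped, so a materially non-zero value flags a measurement
problem.

For amino acids without a tracer, `aa_fluxes()` reports the plain net
balance $(C_a - C_v)\,\mathrm{PF}$ per amino acid and a panel total. The
default panel is the 20 proteinogenic amino acids; 3-MH is always
excluded from totals. Totals are computed on plasma concentrations with
plasma flow — no whole-blood or protein-binding correction is attempted,
matching the plasma-based flow normalization used throughout.

## Plasma flow

During brief venous occlusion the limb swells at the rate of arterial
inflow, so the volume slope in %/min *is* blood flow in ml/min per
100 ml of limb (`slope_to_flow()` only relabels units and rejects
negative or non-finite readings). The pre- and post-sampling series of
ten readings bracket the sampling period symmetrically, so
`occasion_flow()` averages the two phase means rather than pooling the
twenty readings; with equal counts the two rules coincide, and averaging
is robust to an unequal number of valid readings per phase. No automatic
outlier rejection is applied by default — the original measurements were
read by a blinded assessor, which software cannot re-enact — but a
median/MAD trim is available behind a flag. Plasma flow is
$\mathrm{PF} = \text{blood flow}\times(1-\text{hematocrit})$.

## Longitudinal statistics

Two complementary analyses mirror the study design:

* **Period comparison** — occasions in ICU days 10–20 versus days 30–40
  (closed intervals; the protocol's "between days X and Y" is read
  inclusively). To keep the groups independent, a patient studied in
  both periods contributes only the last measurement, and a patient
  studied twice within one period contributes the first
  (`select_observations()`). Groups are compared with a Mann-Whitney U
  test: exact tie-aware enumeration of all assignments when the combined
  sample size is at most 12, and the tie-corrected normal approximation
  with continuity correction otherwise. The exact path is implemented by
  direct enumeration because the classical exact distribution breaks
  under ties; `stats::wilcox.test` serves as an independent reference in
  the tests.
* **Random-intercept model** — `fit_random_intercept()` fits
  $y_{ij} = \beta_0 + \beta_1\,\mathrm{day}_{ij} + b_i + \varepsilon_{ij}$
  by REML (`nlme::lme`), using every occasion. The slope test defaults
  to nlme's within-group $t$: at this design's size (20 patients, 30–40
  observations) the large-sample Wald $z$ alternative is measurably
  anti-conservative (empirical size ≈ 0.075 at nominal 0.05 over 1000
  null replicates), while the within-group $t$ holds its size; the
  `"normal"` option remains available. If the mixed fit is degenerate —
  e.g. an exactly deterministic outcome with no residual variance — the
  fit falls back to ordinary least squares with $\sigma_b = 0$ and is
  flagged.

The **sensitivity refit** removes every patient with any conditional
(within-patient) residual beyond ±3 SD and refits; conditional residuals
are used because the rule is meant to catch aberrant *measurements*
after accounting for a patient's own level. The **zero-crossing day**
of an outcome is $-\beta_0/\beta_1$ with a first-order delta-method SE
from the fixed-effect covariance; slopes below `tol` in magnitude return
an undefined-crossing flag rather than a wild extrapolation. Multiple
outcomes are reported without multiplicity adjustment by default (a Holm
option exists in the configuration).

## The synthetic cohort generator

`generate_cohort()` forward-simulates the *inverse* of the analysis so
that every stage is testable by parameter recovery without any external
data. Its defaults define the study conditions:

* **Schedule** — 20 patients, first occasion at ICU day 10, further
  occasions after uniform 8–12-day gaps, at most 3 per patient,
  censoring at day 40, and a 0.5 per-occasion probability of leaving the
  study (reproducing a cohort of roughly 30–40 occasions with most
  patients studied once or twice). Note a structural consequence: with
  these defaults every occasion falls on or before day 34.
* **Truth** — breakdown $B_i \sim N(80, 10^2)$ nmol/min/100 ml,
  constant in time (the constant-breakdown scenario); net balance
  $\mathrm{NB}(t) = 0.68\,(t-35)$, i.e. ≈ −17 at day 10 rising through
  zero at day 35; synthesis $S_i(t) = B_i + \mathrm{NB}(t)$; inward
  transport $F_{M,A} = B_i$; plasma flow $\mathrm{PF}_i \sim N(3, 0.5^2)$
  constant over the stay; 3-MH efflux $\sim N(3.5, 0.5^2)$ constant;
  arterial concentrations constant in expectation. Truncation of the
  patient-level draws ($\mathrm{PF}_i \ge 2$, $B_i \le 115$) keeps every
  draw inside the model's validity region $F_{M,A} \le C_a\,\mathrm{PF}$.
  These magnitudes are plausible physiological values chosen as
  generator defaults, not measured results.
* **Amino-acid panel** — glutamate is taken up (+8 nmol/min/100 ml at
  day 10), every other amino acid is released in proportion to its
  arterial concentration (12% per unit plasma-flow time), and all efflux
  magnitudes decay as $e^{-0.03\,(t-10)}$, so the total efflux shrinks
  monotonically toward zero. The panel flux of phenylalanine itself is
  the kinetic net balance (the two must agree because they share the
  same samples), which is negative on every schedulable occasion.
* **Noise** — multiplicative lognormal with mean 1: 3% CV on
  concentrations, 2% on enrichments, 10% on individual occlusion
  readings. Lognormal keeps positive quantities positive; the mean-1
  parameterization keeps averages unbiased.

The generator writes the same five CSV tables the loader reads (doubles
serialized at 17 significant digits, so a round trip is bit-exact) plus
a withheld truth table.

What the generator deliberately does **not** emulate: tracer
equilibration kinetics before the 135-minute sampling window (isotopic
steady state is assumed attained; the infusion prime/rate is metadata),
informative dropout (patients leave at random, not because they are
sicker), within-occasion drift (the four timepoints differ only by
noise), leg-volume or composition changes over the stay, and analytical
interference between analytes. Passing recovery tests therefore show
that the *estimators invert the model they assume*, not that real ICU
data satisfy that model.

## Numerical choices and degenerate inputs

* Enrichments are TTR throughout (`ttr_to_mpe()`/`mpe_to_ttr()` convert);
  the kinetic algebra is exact on the TTR scale.
* Enrichment-ordering violations up to $10^{-9}$ (absolute) are clamped
  to the boundary; anything larger raises an error naming the violated
  inequality. Noise can legitimately graze the boundary, but silently
  clamping gross violations would hide bad data.
* A missing biopsy leaves the occasion analyzable by the two-pool model;
  three-pool fluxes are `NA` with `three_pool_ok = FALSE`.
* Steady-state QC flags any analyte series whose CV across the four
  timepoints exceeds 15% (configurable); a zero-mean series is flagged
  as degenerate rather than dividing by zero.
* The amino-acid panel total drops (with a warning) panel members absent
  from the data rather than failing the occasion.
* Negative shunt flow ($F_{V,A} < 0$) is reported with a flag rather
  than an error: it indicates transport estimates inconsistent with
  arterial delivery, a data-quality signal.

## Problem sizes used in the validation suite

The test suite exercises: $10^4$ random flux configurations for the
inversion and dominance properties, 150 ODE-oracle configurations, 200
replicate noisy cohorts (20 patients each) for slope bias, Wald-interval
coverage, the day-35 crossing recovery and the 3-MH null trend, and 1000
null replicates for the size of the slope test and of the Mann-Whitney
test. These sizes give Monte-Carlo error comfortably below the margins
being asserted (e.g. a binomial 95% CI of ±1.4 percentage points on a
5% rejection rate at 1000 replicates).

## Known limitations

* The flow-normalized fluxes are per 100 ml of *leg volume*; loss of
  muscle mass or edema changes the denominator's composition over a
  long ICU stay in ways the models cannot see.
* The two-pool model's rates are systematically below the three-pool
  rates (the recycling gap); they are useful for *trends*, which is
  exactly how the package's longitudinal layer treats them.
* No blood-water or protein-binding correction is applied to
  concentrations before the balance equations.
* The Mann-Whitney exact path enumerates all assignments and is
  intentionally limited to small combined sample sizes (default ≤ 12).
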