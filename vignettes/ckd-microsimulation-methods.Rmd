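---
title: "Comparing grade-based and kidney function-based CKD microsimulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing grade-based and kidney function-based CKD microsimulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdmicrosim)
```

## The modelling question

Cost-effectiveness analyses of chronic kidney disease (CKD) interventions
are usually built on individual-level state-transition models
(microsimulations), and the field uses two structurally different designs.
A *disease grade-based* microsimulation (here `dg`) treats the KDIGO CKD
grades G1--G5 as discrete health states and lets patients hop to the
next-worse grade with a per-cycle probability that depends on the grade
only. A *kidney function-based* microsimulation (`kf`) instead carries the
estimated glomerular filtration rate (eGFR, mL/min/1.73 m²) as a
continuous severity variable that declines linearly at a patient-specific
rate, and derives the grade — and with it mortality, cost, and utility —
from the current eGFR. The two designs encode different beliefs about
disease progression, and this package exists to quantify how much that
structural choice alone moves the quantities a health-economic analysis
reports: life-years, discounted QALYs and costs, renal survival, and the
intervention-price thresholds V0 and V1 defined below.

## The two simulators

Both models share a virtual cohort of equal numbers of 37-year-old men and
women with an initial eGFR of 73 mL/min/1.73 m², quarterly cycles
(nephrology practice follows CKD patients with an eGFR measurement about
every three months), and an age cap of 110 years that guarantees
termination. Mortality is a Gompertz-type annual hazard
$a\,e^{b\cdot\text{age}}$ with sex-specific coefficients, multiplied by a
grade-specific hazard ratio (1.0 for G1/G2 rising to 5.9 for G5);
dialysis-dependent patients use a separate coefficient pair with no sex
term and no grade multiplier. We read these published formulas as *annual*
hazards — their magnitudes match general-population and dialysis mortality
on an annual scale — and convert them to per-cycle probabilities with the
exponential formula $p = 1 - e^{-r\,c}$, which makes survival consistent
under any subdivision of the cycle.

In the kidney-function model every patient draws one constant annual
decline slope from a log-normal distribution (no patient improves
continuously), parameterised by moment matching from the published mean
and SD of the decline speed: control 2.2 ± 6.5, intervention 1.3 ± 8.5
mL/min/1.73 m²/year. Within a cycle the order of operations is: death
test at the current age and state, then eGFR moves along its line, then
the grade is recomputed; the cycle's cost and utility accrue afterwards in
the post-transition state, discounted at the cycle-start time. This
ordering follows the flowchart convention of such models (survival is
decided first; period rewards are added after the state transition is
determined). A patient whose eGFR has fallen to the renal replacement
threshold (7 mL/min/1.73 m²) starts dialysis permanently: eGFR is no
longer tracked, and dialysis mortality, cost (84.6 thousand USD/year) and
utility (0.72) apply for the remainder of life.

Two numerical details matter here. First, eGFR is updated by the closed
form $\text{eGFR}_0 - s \cdot t$ rather than by repeated subtraction, so
the crossing time of any band boundary is exact to machine precision;
with the base slope 2.2 the renal replacement threshold is reached at
exactly $(73-7)/2.2 = 30$ years (120 quarters). Second, the grade bands
are closed at their lower bound (an eGFR of 45 is G3a, mirroring the
published band "45--59"), while the renal replacement threshold is reached
*inclusively*: a patient whose eGFR falls exactly to the threshold at a
cycle boundary starts dialysis in that cycle. This makes the simulated
crossing-cycle count equal the ceiling of the analytic crossing time over
the cycle length in all cases, including exact division.

The grade-based model shares the mortality, economics and cycle structure
but replaces the eGFR line with a per-grade progression probability: each
cycle a surviving patient moves to the next-worse grade with the current
grade's probability (G5's target is the dialysis state). No regression to
milder grades is allowed, and by default no grade skipping — the chain
topology of the published state diagram. The full from--to matrix observed
during translation can optionally be used instead
(`estimate_transitions(collapse = FALSE)`), which permits multi-grade
jumps; the default collapses such jumps into a single next-grade event.

## Translation: one model calibrated from the other

Comparing the designs fairly requires that both run under the *same*
epidemiology. The kidney-function model is taken as the reference (its
inputs are cohort-level decline statistics published directly), and the
grade-based model's transition probabilities are estimated from the
kidney-function model's simulated trajectories, separately per arm, the
way such probabilities are estimated from real patient records: compare
each patient's grade at two consecutive visits and take the fraction who
progressed among the patients observed in a given grade. Pairs ending in
death are excluded, because the grade-based model applies its own
mortality; a transition spanning several grades counts once, from its
source grade. The calibration cohort is simulated independently of the
evaluation cohorts, with its own random substream.

The phrase "fraction of patients in a grade who progress by the next
visit" hides a genuinely consequential estimator choice, because the
simulated population is extremely heterogeneous (the log-normal slope
distribution has median 0.71 but mean 2.2 and SD 6.5):

* **Per-patient weighting** (`weighting = "patient"`, the default): each
  patient observed in grade $g$ contributes its progression indicator
  divided by its number of visit pairs in $g$ — the expectation of
  sampling one random visit pair per patient, which is what reading a
  fraction of *patients* off a registry corresponds to.
* **Pair pooling** (`weighting = "pair"`): all alive--alive pairs are
  pooled. A patient's pair count in a grade scales inversely with their
  slope, so slow decliners dominate and the estimated probabilities are
  several times smaller.

The choice moves the grade-based model's absolute results substantially
(the two weightings bracket a factor of ~4 in progression speed). The
per-patient default reproduces the reference comparison's headline
structure — the grade-based model showing shorter life-years, lower
utilities, higher costs, and threshold statistics within tolerance of the
kidney-function model's — whereas pair pooling inverts the cost ordering.
Users studying estimator sensitivity can switch weightings, thin the pair
list (`subsample_fraction`) to mimic literal random sampling, or use the
full-matrix variant.

Why do the translated grade-based results differ from the kidney-function
results at all? Constant per-grade probabilities erase two features of the
continuous model: within-grade position (a cohort entering G3a near its
lower boundary has, in truth, a rising hazard of crossing as time passes)
and between-patient speed (in the kidney-function model, the patients who
reach deep grades are the fast decliners, whereas the memoryless chain
sends a mixture). The first effect makes grade-based progression too fast
early in a grade; the second concentrates or spreads dialysis onset
differently across the lifespan. These are exactly the structural biases
the package is meant to expose.

## Economic outcomes and the V0/V1 thresholds

Per surviving cycle a patient accrues the state's annual utility weight
times the cycle length, discounted by $(1+r_u)^{-t}$ with $t$ the years
elapsed at the cycle start, and analogously the state's annual cost at the
cost discount rate (both rates 3%/year by default). The cycle in which
death occurs accrues nothing, and no half-cycle correction is applied —
the models' flowcharts describe plain per-period addition. "Life-years"
are reported as the mean *age* at death (starting age plus survived
time), matching the scale of the published results; reaching the age cap
counts as end of accrual and censoring, not death.

For a control arm with mean discounted cost $C_a$ and QALYs $U_a$ and an
intervention arm with $C_b$, $U_b$ (intervention cost excluded), the
package reports

$$V_0 = C_a - C_b, \qquad V_1 = \lambda\,(U_b - U_a) + (C_a - C_b),$$

with willingness-to-pay $\lambda$ = 50 thousand USD/QALY by default. V0 is
the intervention price below which the intervention is *dominant* (costs
less overall, assuming it yields more utility); V1 the price below which
it is *cost-effective* at $\lambda$. The identity
$V_1 - V_0 = \lambda (U_b - U_a)$ holds exactly and is asserted in the
test suite on every run.

Renal survival — the probability of not yet requiring renal replacement
therapy — is estimated with the Kaplan–Meier product-limit estimator
(Greenwood variance); death before dialysis and the age cap censor. This
matches conventional nephrology reporting, where death is censored rather
than treated as a competing risk.

## Sensitivity analyses

Every parameter with a published uncertainty range can be varied. One-way
analysis walks each parameter over an even grid between its limits with
everything else at base and the same random seed per evaluation, so
differences across the grid reflect the parameter alone. The probabilistic
analysis samples every ranged parameter independently and *uniformly*
within its limits — the limits are the only published uncertainty
information, so no more informative distribution is defensible — and
summarises the between-model differences by their 2.5th–97.5th
percentiles. Utility draws are deliberately not forced to be monotone
across severity states; occasional inversions are possible and retained.

Mortality-formula uncertainty is expressed as multiplicative modifiers
(×0.8–×1.2) applied to the baseline coefficient $a$. The intervention
arm's decline distribution is re-derived inside sensitivity runs from the
control arm via the slope improve rate (intervention mean = control mean ×
improve rate) with the base-case SD ratio (8.5/6.5) held fixed, so varying
the control decline or the improve rate moves both arms coherently.

## Problem sizes, seeds, defaults

The base-case comparison uses $10^5$ patients per cohort (six cohorts per
run: per arm one calibration and two evaluation cohorts); at that size the
Monte-Carlo standard error of mean life-years is about 0.04 years and of
mean cost about 1 thousand USD. Sensitivity evaluations default to
$2 \times 10^4$ patients per cohort, which keeps a 200-draw probabilistic
analysis at desk scale while leaving parameter effects well above noise.
Every cohort receives its own substream seed derived from the master seed,
so any result is reproducible from (parameters, seed) alone; odd cohort
sizes randomise the extra patient's sex from the same stream.

The initial eGFR defaults to 73 mL/min/1.73 m² (the tabulated base case;
the published text also mentions 76, available as
`ckd_parameters(initial_egfr = 76)`). With eGFR below 90 the cohort never
occupies G1, so G1-specific parameters are held fixed in the sensitivity
analyses.

## What the generator does and does not emulate

The simulators themselves are the data generators: they emulate constant
per-patient eGFR decline, grade-dependent mortality, and stationary costs
and utilities. They do not model non-linear or time-varying decline,
kidney transplantation as a replacement modality, cardiovascular or
demographic covariates beyond age and sex, or secular changes in dialysis
cost. Passing tests therefore demonstrate internal consistency and
faithful reproduction of the reference comparison's structure, not
validity for any specific real-world CKD population.

## Known limitations

* The translated grade-based model's *absolute* life-years and costs
  depend strongly on the transition-estimator weighting (see above); the
  reference publication's exact sampling procedure is not recoverable
  from its text, and the two faithful readings bracket its published
  absolute values. Between-model threshold statistics and all direction
  claims are robust to the choice.
* Transition probabilities are stationary within a grade; age- or
  time-varying transition tables are out of scope.
* The dialysis state is absorbing — recovery of kidney function and
  transplantation are not modelled.

## A minimal run

```{r example, eval = FALSE}
params <- ckd_parameters(cohort_size = 2e4)
cmp <- run_paired_comparison(params, seed = 1)
glance(cmp)     # one row per model: life-years, QALYs, costs, V0, V1
tidy(cmp)       # long per-metric table with SDs
autoplot(cmp)   # renal-survival curves for all four cohorts
```
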