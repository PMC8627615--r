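---
title: "Modelling metabolic syndrome natural history with Markov and stock-and-flow engines"
author: "msdmets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metabolic syndrome natural history with Markov and stock-and-flow engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdmets)
set.seed(1)
```

## The model

Metabolic syndrome (MetS) is diagnosed when three or four of its
defining components — abdominal obesity, hypertension, dyslipidemia
(high triglycerides with low HDL) and hyperglycemia — co-occur. Before
that point a person occupies one of eleven precursor states: no
component, one of the four isolated components, or one of the
`C(4,2) = 6` component pairs. Together with MetS itself (a single
merged state for "three or four components") this gives a 12-state
space, stratified into *tiers* by component count (0, 1, 2, MetS).
`mets_states()` enumerates it in a fixed canonical order — tier first,
then alphabetical label — so matrices from different runs are always
comparable.

Movement between states over successive examination waves (roughly
triennial in TLGS-style cohorts) is treated as a first-order
multistate process. Two prediction engines share the same estimated
transition probabilities:

* **Markov engine.** Per wave pair, the transition probability from
  state *i* to *j* is the observed fraction of persons in *i* who are
  in *j* one wave later (`count_transitions()` + `estimate_tp()`).
  The final matrix is the arithmetic mean of the per-period matrices
  with the MetS row replaced by an absorbing unit vector
  (`average_tp()`). Occupancy after *t* periods is `initial %*% P^t`.

* **MSD (stock-and-flow) engine.** Each state is a stock; each nonzero
  transition-probability cell defines a flow. Flows are classified by
  `classify_flow()`: forward (`TPO_F`, to a higher tier), backward
  (`TPO_B`, recovery), stay-in-state (`TPI`) and lateral (`TPW`,
  within a tier — 21 unordered pairs, 6 among isolated components and
  15 among pairs). During one period a state holding `N` persons sends
  `N × TP × FR(tier)` along each forward flow and `N × TP × CR(tier)`
  along each backward flow; lateral flows are unmodulated
  (`N × TP`). Integration is forward Euler with one step per triennial
  period (`substeps` refines this if wanted).

The control rate CR and failure rate FR summarise, per tier, how well
the population's progression is being held in check. FR is the
fraction of at-risk person-transitions from a tier that move to a
higher tier in one period; CR = 1 − FR counts staying *and* regressing
as controlled. They are estimated separately in two intervention
strata — lifestyle-programme participants, and persons reporting
medication use — with two exclusions: MetS occupants contribute only
the MetS tier's own regression rate, and no-component persons are
excluded from the medicinal stratum because no medication is indicated
for healthy individuals. Stratum values are combined by unweighted
mean (a person-weighted mean is available), then averaged over wave
pairs.

```{r rates}
cohort <- generate_cohort(cohort_config(n_people = 3000, seed = 1))
estimate_cr_fr(cohort$panel)
```

## Numerical and design choices

**Residual-mass closure.** Modulated outflows are smaller than the raw
Markov flows, so some mass is never sent anywhere; it remains in the
origin state. This is the only closure that conserves a closed
population, and it has a useful consequence: when every CR and FR is
set to 1 the stock update collapses to `N %*% P`, so the MSD engine
must reproduce the Markov matrix-power trajectory to within 1e-9. That
equivalence is enforced in the test suite and is the main correctness
oracle for the integrator.

**Progression rates.** Both engines report, per origin state, the rate
of progression toward MetS: new MetS entries during a period for a
cohort that started the horizon in that state, divided by its at-risk
(non-MetS) person-years, with person-years measured at the start of
the period. Under an absorbing Markov matrix these per-origin curves
rise and then flatten onto a common quasi-stationary level, the
expected signature of an absorbing multistate process.

**Absorbing MetS is an engine flag, not a fact.** The Markov engine
follows the convention of declaring MetS absorbing in its final
matrix; real cohorts show substantial regression out of MetS (the
reference table's MetS stock implies it, and the MetS control rate is
far from zero). The MSD engine therefore treats MetS as non-absorbing,
with a recovery flow modulated by the MetS regression rate. Both
behaviours are arguments, not hard-coded.

**Degenerate rows.** A state with nobody at risk in some wave pair
gets the identity row (stay with probability 1), keeping every matrix
row-stochastic. Averaged matrices are re-normalised row-wise as a
guard; the tolerance everywhere is 1e-9.

**Reference-table arithmetic.** The bundled TLGS wave counts
(`tlgs_state_counts()`) sum to exactly 12,882 at every wave. Their
published percent-change column is reproduced by *truncating* the
exact percent change toward zero at one decimal; `percent_change()`
implements both that convention and the exact value.

**Hold-out validation.** `holdout_predict()` refits on all waves but
the last and predicts the held-out wave for the cohort observed at
both of the final two waves, so predicted and actual occupancies count
the same people. Four comparison criteria follow: mean signed
difference and the standard error of the paired differences (over the
144 matrix cells by default, or the 12 occupancies), the asymptotic
two-sample Kolmogorov–Smirnov test and R² of actual on predicted
(both over the 12 occupancies; with 12 values the asymptotic KS
p-value is approximate). In a closed population the signed mean
difference is conserved to zero on either basis — both predicted and
actual vectors have fixed totals — so that criterion ties by
construction and discrimination comes from the other three.

## What the synthetic generator does and does not emulate

`cohort_config()` defaults describe a TLGS-like study: 12,882 persons,
five waves spanning 16 years, baseline prevalences taken from the
published baseline counts (isolated dyslipidemia largest), a
tier-structured generating matrix whose dominant moves out of
`no_component` are into isolated components, a MetS row that keeps
0.60 in place and regresses the rest (matching the observed ~0.6
stay-in-MetS and ~0.4 regression magnitudes), per-component medication
flags (probability 0.3 per present component), and a 20%
lifestyle-intervention subgroup whose backward transition
probabilities are inflated 1.5-fold (rows re-normalised). Draws are
ordered person-major so enlarging a cohort never perturbs existing
persons.

The generator deliberately omits attrition, staggered entry, age/sex
structure, continuous biomarkers and time-varying dynamics: its world
is an exactly first-order, time-homogeneous mixture of two Markov
chains. Passing tests therefore demonstrate estimator and integrator
correctness, not that real cohorts satisfy those assumptions.

Two test-design consequences follow. First, parameter recovery of a
known matrix to ±0.02 per cell is checked on a cohort designed to
power that bound: a uniform baseline over the 12 states and 13 waves
put roughly 10,000 at-risk transitions behind every matrix row, making
0.02 about a 4-sigma binomial bound per cell. Under the TLGS-like
baseline such a bound is unattainable for rows fed by the rarest state
(hypertension + hyperglycemia, baseline prevalence 0.2%) — a fact
about sampling error, not about the estimator. Second, because the
synthetic truth *is* Markov, the Markov engine is nearly the true
model there, and the engine comparison behaves accordingly: the MSD
engine wins the occupancy-based mean SE and KS criteria (the absorbing
assumption costs the Markov engine heavily on MetS-related
occupancies) while the Markov engine retains a slightly higher R².
The MSD engine's advantage on all criteria at once should only be
expected on data whose dynamics drift over time in the way real
intervention-bearing cohorts do.

## A short worked run

```{r run}
hz <- horizon(2015, 2036, 3)
tp <- estimate_avg_tp(cohort$panel, absorbing = TRUE)
init <- as.numeric(table(factor(
  cohort$panel$records$state[cohort$panel$records$wave == 4],
  levels = state_labels())))
predict_markov(tp, init, hz)
predict_msd(cohort$panel, hz)
compare_models(cohort$panel, basis = "occupancy")
```

## Known limitations

* First-order dependence is assumed; second-order structure in real
  cohorts is not modelled.
* Transition probabilities are unadjusted — no age, sex or covariate
  effects.
* The CR/FR modulation multiplies estimated transition probabilities,
  so the effective MSD flows are systematically smaller than the
  observed flows whenever FR < 1; this damping is intrinsic to the
  formulation, and the fr = cr = 1 limit is the exact Markov case.
* The asymptotic KS p-value on 12 occupancy values is approximate;
  treat it as a ranking device between engines rather than a
  calibrated test.
```
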