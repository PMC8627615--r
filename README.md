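# msdmets

Modelling the natural history of metabolic syndrome (MetS) as a
12-state multistate process, with two interchangeable prediction
engines: a discrete-time **Markov chain** and a **system-dynamics
stock-and-flow simulation** whose flows are modulated by per-tier
control and failure rates.

## Who this is for

Epidemiologists and biostatisticians working with longitudinal panel
data on MetS (or any staged condition defined by co-occurring
components) who want to estimate transition probabilities between
component states, project state occupancies and progression rates
years ahead, and compare a classical Markov projection against a
hybrid Markov/system-dynamics one that folds intervention effectiveness
into the flows.

## The model in brief

A person occupies one of 12 states defined by which MetS components —
abdominal obesity, hypertension, dyslipidemia, hyperglycemia — are
present: *no component* (tier 0), 4 isolated components (tier 1),
6 component pairs (tier 2), and MetS itself (three or four components,
tier 3). Over triennial examination waves, transitions are estimated
per wave pair by count-based row normalisation,

&nbsp;&nbsp;&nbsp;&nbsp;p̂ᵢⱼ = nᵢⱼ / nᵢ₊ ,

and averaged into a final 12×12 row-stochastic matrix **P** (MetS row
absorbing in the Markov engine). Occupancy after *t* periods is
**N**₀**P**ᵗ.

The MSD engine replaces the matrix power with explicit stocks and
flows. Per tier, the failure rate FR is the fraction of at-risk
person-transitions that progress to a higher tier in one period and
CR = 1 − FR; both are estimated within lifestyle and medication
intervention strata and averaged. During one period each state sends

* `N × TP × FR(tier)` along forward (progression) flows,
* `N × TP × CR(tier)` along backward (recovery) flows,
* `N × TP` along lateral (within-tier) flows — 21 unordered pairs,

and keeps the unsent remainder (the population-conserving closure).
With all CR = FR = 1 the simulation reduces exactly to the Markov
matrix-power prediction — the built-in correctness oracle.

A hold-out protocol fits either engine on all waves but the last,
predicts the held-out wave, and scores four criteria: mean signed
difference, standard error of the paired differences, two-sample
Kolmogorov–Smirnov, and R² of actual on predicted.

A synthetic cohort generator (`cohort_config()`, `generate_cohort()`)
produces TLGS-like panels — 12,882 persons, five waves, published
baseline prevalences, medication flags and a lifestyle subgroup with
inflated recovery probabilities — with known ground truth, so every
estimator in the package is testable end to end.

## Worked example

```r
library(msdmets)

cohort <- generate_cohort(cohort_config(n_people = 3000, seed = 1))
cohort$panel
#> MetS panel: 15000 records, 3000 persons, 5 wave(s)
#> wave years: 1999, 2003, 2007, 2011, 2015

estimate_cr_fr(cohort$panel)
#> Control and failure rates (%):
#>    no_component one_component two_component  mets
#> CR        46.54         65.28         65.08 48.93
#> FR        53.46         34.72         34.92    NA

tp <- estimate_avg_tp(cohort$panel, absorbing = TRUE)
round(tp["no_component", c("no_component", "obesity", "mets")], 3)
#> no_component      obesity         mets
#>        0.506        0.105        0.026

init <- as.numeric(table(factor(
  cohort$panel$records$state[cohort$panel$records$wave == 4],
  levels = state_labels())))
predict_markov(tp, init, horizon(2015, 2036, 3))
#> MetS trajectory (markov engine): 7 period(s), 2015-2036
#> final MetS occupancy: 2464.0 of 3000.0 persons

compare_models(cohort$panel, basis = "occupancy")
#> Engine comparison (basis: occupancy for diff/SE)
#>   markov mean_diff=-0.00000 mean_se=35.218755 ks_p=0.100 R2=0.994
#>   msd    mean_diff=-0.00000 mean_se=7.576825 ks_p=0.996 R2=0.992
#> criterion winners: mean_difference=tie, mean_se=msd, ks_pvalue=msd, r_squared=markov
#> overall: msd
```

Reading the output: a 53% tier-0 failure rate means half the
no-component population acquires at least one component within a
period; estimated one-step probabilities out of `no_component` go
mostly to isolated components, with 2.6% straight to MetS; under an
absorbing Markov projection 2,464 of 3,000 persons occupy MetS by
2036; and on the held-out wave the stock-and-flow engine tracks the
occupancy distribution more closely (smaller SE of differences, higher
KS p-value) while the Markov engine keeps a marginally higher R². The
signed mean difference ties at zero because both engines conserve the
closed cohort.

A command-line wrapper with `synth`, `estimate`, `rates`,
`predict-markov`, `predict-msd`, `validate` and `compare` subcommands
is installed at `inst/cli/msdmets.R`:

```sh
Rscript inst/cli/msdmets.R synth --n-people 1000 --seed 7 --out panel.csv
Rscript inst/cli/msdmets.R predict-msd --input panel.csv --out traj.csv
```

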