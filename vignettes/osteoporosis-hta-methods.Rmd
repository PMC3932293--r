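---
title: "Methods: health-economic modelling of antiosteoporotic treatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: health-economic modelling of antiosteoporotic treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteohta)
```

`osteohta` implements the computational core of a health-technology
assessment of denosumab for the prevention of osteoporotic fractures in
postmenopausal women, from the perspective of the Italian National Health
Service: a lifetime Markov cohort cost-effectiveness model with
probabilistic sensitivity analysis, a three-component budget-impact model
comparing drug-market scenarios with and without denosumab, and a
hospitalization burden-of-illness calculator. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices
made where the published inputs end and synthetic ones begin.

## The Markov cohort model

A cohort of women enters the model at age 65 in the no-fracture state and
is propagated in six-month cycles through seven health states: healthy
(no fracture), hip/femoral fracture, the period after a hip fracture,
vertebral fracture, the period after a vertebral fracture, other
(non-hip non-vertebral) fracture, and death. Occupancy moves through a
row-stochastic transition matrix per cycle; fracture states last one cycle
(a hip fracture flows to the post-hip state, a vertebral fracture to the
post-vertebral state, an other fracture returns to the no-fracture state),
post-fracture states permit re-fracture at the treated baseline risk, and
death is reachable from every state.

Internally the two post-fracture states are each split into a *recent*
phase (months 6–12 after the event) and an *established* phase. This
tunnel carries two first-year effects without enlarging the reported state
space: first-year versus subsequent-year utilities, and the excess
mortality multiplier (default 2.0) applied to background mortality during
the first year after a hip fracture. `build_transition_matrix(expanded =
TRUE)` exposes the 9-state internal matrix; the default 7-state view uses
the established-phase rows for the merged states.

Treatment modifies the fracture entry probabilities multiplicatively:
`p_treated = p_baseline * (1 - RRR * w)`, where RRR is the drug's relative
risk reduction for that fracture type and `w` is the efficacy weight in
force: 1 while on treatment, decaying linearly to 0 over the *offset time*
after discontinuation. Compliance splits the cohort at baseline: a
compliant fraction receives drug cost and full efficacy for the treatment
duration (base case 5 years) followed by offset decay (base case 1 year),
while the noncompliant fraction pays for and benefits from a single cycle
before its own offset decay. This is the simplest split consistent with
efficacy and compliance jointly driving outcomes; both arms are exposed in
the trajectory object for inspection.

Transition rows are validated, never renormalized: inputs whose fracture
and death probabilities sum above one raise a construction error naming
the row. Occupancy conservation is checked at every cycle to `1e-12`, and
the dead fraction is monotone by construction.

### Economic accumulation

Per cycle, costs comprise drug acquisition (half the annual price per
on-treatment cycle, paid by the fraction alive at the cycle start) and
acute fracture costs: because fracture states last exactly one cycle,
state occupancy equals the fraction of the cohort fracturing that cycle,
so occupancy times the unit cost prices the events. Quality-adjusted time
is occupancy times the state utility times half a year. Costs and QALYs
accruing in cycle *k* are discounted by `(1 + r)^(-k/2)` with `r = 3%`
per year. A half-cycle correction is available as a flag
(`half_cycle = TRUE`, averaging adjacent occupancies and discounting
mid-cycle for the QALY stream) and is off in the base case.

Published inputs: acute costs of 8,206 EUR (hip) and 2,476 EUR
(vertebral); the other-fracture state pools a published six-site cost
sub-table with configurable mix weights (default weights emphasise
forearm, humerus and pelvis, giving roughly 3,690 EUR); utilities 0.700 /
0.800 (hip, first / subsequent years), 0.590 / 0.929 (vertebral), 0.902
(other fractures, first year). The utility of the no-fracture state is
not published; the package sets it to 1.0 so that every printed
post-fracture utility acts as a decrement from full health — with a lower
reference (e.g. an age-adjusted population norm of 0.81) the subsequent
vertebral utility of 0.929 would paradoxically reward fractures.

Incremental results follow `ICER = (C_int - C_comp) / (Q_int - Q_comp)`,
with explicit `dominant` / `dominated` / `infinite` / `indifferent`
statuses instead of exceptions in the degenerate quadrants.

### Probabilistic sensitivity analysis

`run_psa()` jointly redraws unit costs (Gamma, 20% CV), utilities (Beta,
sd 0.03–0.05), per-product compliance (Beta, sd 0.05), per-product
relative risks (log-normal on the risk-ratio scale, sdlog 0.15), a common
fracture-risk multiplier (log-normal, sdlog 0.10), the post-hip mortality
multiplier (log-normal, sdlog 0.15, rejected below 1), offset time
(uniform 0.5–1.5 years, centred on the base case) and treatment duration
(uniform 3–7 years). The publication names the varied quantities but not
their distributions; these families are the conventional choices for
bounded, positive and ratio-scale quantities respectively. Out-of-domain
draws are rejected and resampled with the count reported. Degenerating
every distribution to a point mass reproduces the deterministic result
exactly, which the tests assert. The acceptability curve counts draws
with strictly positive net monetary benefit `threshold * ΔQ - ΔC`; an
exactly zero benefit conservatively counts as not cost-effective.

## Synthetic backgrounds: what is emulated, and what is not

The publication does not print baseline fracture incidence, background
mortality, or the demographic series behind its forecasts. The
`synthetic_inputs` generators stand in for them and are first-class,
tested code:

* **Life table** — Gompertz mortality, `q6(x) = 1 - exp(-0.5 a e^{b(x+1/2)})`
  (the hazard is evaluated at mid-year so the piecewise-constant table
  integrates the continuous law; the summed survival curve matches the
  continuous Gompertz life expectancy to well under 0.1 years). Defaults
  `a = 4e-6`, `b = 0.115` give a remaining life expectancy at 65 of about
  21.4 years, typical of Italian women around 2010. The terminal age (110)
  carries probability 1.
* **Baseline fracture hazards** — exponential age gradients anchored at a
  reference age. For the budget-impact model the level is *calibrated*:
  `make_baseline_hazards()` back-solves the annual probability per type so
  that the treated population, under each product's compliance-weighted
  efficacy, experiences the target national fracture counts. Only the
  product of hazard and exposed population is identifiable; the exposure
  is fixed first and the hazard solved conditional on it. At extreme ages
  mortality crowds out the fracture hazards: the curves are scaled into
  the room left by death so every transition row stays stochastic, which
  is why the age-monotonicity of the hip hazard is only guaranteed below
  about age 100.
* **Population projection** — a geometric per-band projection of women
  aged 45+. The default base (28.72 million) is back-solved from the
  published total discharge rate (35.60 per 100,000 against 10,225
  admissions); growth is bounded to ±5% per year.

These generators emulate levels and age gradients, not real data: no
secular trends, no individual-level heterogeneity or frailty, no
seasonal or regional structure, and no attempt to reproduce actual
national statistics beyond the back-solved anchors. Passing tests
therefore demonstrate internal consistency and correct mechanics — that
calibration targets are recovered, invariants hold, and published
arithmetic closes — not predictive validity on real Italian data.

## The budget-impact model

Three deterministic components compose: the demographic projection, the
disease model (`treated = population x prevalence x treatment rate`), and
the technology-prediction model (per-product patient counts via the
published market-share table). The published forecast pins denosumab at
60,000 patients in its first market year (2.3% share) and 150,000 in the
third (8.0% share); since `count / share` then implies different total
market sizes (2.61M vs 1.88M), `calibrated_uptake()` reproduces both
anchors exactly by letting the per-year treatment rate move, at the cost
of a non-monotone treated population. The package treats the two printed
anchors as binding and documents the inconsistency rather than resolving
it.

The counterfactual ("without denosumab") redistributes denosumab's share
over the products it displaces — by default strontium ranelate (66%),
oral ibandronate (31%) and the alendronate/cholecalciferol combination
(3%), proportions derived from the published per-product spend erosion.
Expected fracture counts are expectation-based
(`patients x p_annual x (1 - RRR x compliance)`); a binomial sampling
mode exists for uncertainty runs. Costs fall into four payer categories:
medications (noncompliant patients pay for six months), inpatient care
(acute DRG cost at the event), outpatient care (per-event, same year) and
community care (per-event, lagged one year — which is why the first
impact year shows no community component). Impacts are reported as
`with - without` in thousands of EUR, rounded half-away-from-zero, with
negative values denoting savings.

Two published quantities cannot be regenerated from printed inputs and
are deliberately out of scope: the absolute per-product spend table
(requires unprinted unit prices) and the sign of the published total
impact under our sum-to-one redistribution. The published without-world
grew the expensive comparators far beyond denosumab's own share (the
strontium spend erosion alone implies more displaced patient-equivalents
in the final year than denosumab's entire patient count), an assumption
the publication does not print. With the package's synthetic prices the
default computed impact is a net cost; the published per-category deltas
are shipped as a fixture and all headline arithmetic (totals, avoided
fractures, the inpatient share of avoided costs) is computed from them by
the same functions.

Annual drug prices are synthetic throughout. Denosumab's 427
EUR/patient-year is back-solved from published budget arithmetic (the
medications delta plus the comparator spend changes, over 60,000
patients); the others are order-of-magnitude calibrations of published
spend over share-implied patient counts, and all are config-overridable.

## The hospitalization burden module

DRG-tariff admission records aggregate to per-type counts and cost
totals; monetary accumulation converts tariffs to integer cents before
summation so national totals reproduce to the cent regardless of record
order. The record generator emits per-type counts exactly and rescales
drawn tariffs to hit the cost marginals to the cent (the rounding
residual lands on the largest record), so different seeds move individual
tariffs but never the marginals. Discharge rates divide admissions by a
population denominator per 100,000; the denominators behind the published
rates are not printed, and the back-solved values used in tests are
labelled synthetic.

## The calibration demonstration

The published cost-effectiveness results (total costs of 22,399 EUR and
10.46 QALYs for denosumab, ICERs of 69–18,047 EUR/QALY, acceptability
probabilities of 65–95%) depend on unprinted baseline hazards, mortality,
prices and PSA distributions, and are not desk-reproducible. The package
therefore treats the Markov engine's correctness as a property-testing
question (conservation, matrix-power equivalence, exact limits,
monotonicity) and, separately, demonstrates that the published
*qualitative* ordering is attainable: `cea_background()` is a documented
synthetic background — annual fracture probabilities at 65 of 2.5% (hip),
7% (vertebral) and 6% (other), plausible for a severe-osteoporosis
(T-score below −4) cohort and calibrated for this demonstration — under
which denosumab gains QALYs against all five comparators, is
cost-effective at 30,000 EUR/QALY against all of them, and is nearly
cost-neutral against strontium ranelate (ICER around 600 EUR/QALY). No
exact published value is asserted.

## Numerical choices

* Conservation tolerance `1e-12` per cycle; construction errors, never
  silent renormalization, for infeasible rows.
* The excess-mortality product `q x m` saturates at 1 rather than
  overflowing the row.
* Exact cent arithmetic for hospital cost sums; `round half away from
  zero` for thousands-EUR reporting.
* Ties in net monetary benefit count against cost-effectiveness.
* The cohort runs to extinction (dead fraction within `1e-9` of 1) or age
  110, whichever comes first.
* Market-share columns are validated to sum to 1 within 1% before exact
  normalization — printed share tables rounded to 0.1 percentage points
  legitimately sum to 99.9%.

## Problem sizes

The test suite runs lifetime cohorts (90 six-month cycles) for a handful
of strategies and keeps PSA runs to tens of draws; the acceptance script
uses 300 PSA draws across six strategies and a 236,000-record admission
synthesis. These sizes were chosen as the smallest that exercise every
code path with stable Monte-Carlo summaries; all deterministic quantities
are size-independent.

## Known limitations

* NHS perspective only: no societal or caregiver costs, matching the
  source analysis's own scope.
* The compliance split is all-or-nothing at baseline; real adherence
  decays continuously.
* Re-fracture risks in post-fracture states equal the baseline (treated)
  risk; no risk amplification after a first fracture.
* The budget-impact counterfactual is a sum-to-one redistribution of
  denosumab's share; scenario share tables with independent growth
  assumptions must be supplied by the user.
* All synthetic backgrounds are deterministic stand-ins, not estimates
  from Italian registry data.
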