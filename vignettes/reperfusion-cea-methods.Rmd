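---
title: "Modelling the lifetime economics of reperfusion quality after thrombectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the lifetime economics of reperfusion quality after thrombectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeCEA)
```

## The question

Endovascular thrombectomy (EVT) for large-vessel-occlusion stroke does not
always end in complete reperfusion. Final reperfusion is graded on the
eTICI scale; a grade of 2b ("successful" but incomplete) carries
measurably worse 90-day functional outcomes than near-complete 2c/3.
Incomplete patterns divide further into those with a residual occlusion a
neurointerventionalist could still reach (EVT-accessible) and those with
only small distal occlusions or slow flow (EVT-non-accessible, candidates
for intra-arterial pharmacological rescue). strokeCEA asks what converting
those incomplete patterns into complete reperfusion would be worth — per
patient over a lifetime, and per year at national scale.

## Model structure

The model is a two-phase Markov cohort model over seven health states:
modified Rankin Scale (mRS) grades 0–5 plus absorbing death.

**Short-run phase (one 3-month cycle).** Each strategy arm (reperfusion
pattern) is defined by its 90-day mRS distribution; mRS 6 maps to death.
The cohort accrues a quarter-year of state utility over surviving states
and the acute costs: the EVT procedure, the arm's expected intravenous
alteplase use, other acute hospital care, and a quarter-year of
state-dependent care costs.

**Long-run phase (annual cycles).** From the 90-day distribution the
cohort evolves through annual transitions until extinction at the end of
the life table. In each cycle a patient in living state $s$ at age $x$
can:

* die, with probability
  $P(D) = 1 - (1 - q_x h_s)(1 - p_{rec} \cdot cf)$, combining background
  mortality $q_x$ (life table) scaled by the state's hazard ratio $h_s$
  with fatal recurrent stroke ($p_{rec}$ annual recurrence probability,
  $cf$ its case fatality), the two risks treated as independent within a
  cycle;
* deteriorate after a non-fatal recurrence, with probability
  $(1 - q_x h_s)\, p_{rec} (1 - cf)\, W(s, s')$ for $s' > s$, where $W$
  truncates a post-stroke mRS distribution to grades at least as bad as
  the current one and renormalises;
* otherwise remain in state.

Conditioning the deterioration flow on surviving background mortality is a
deliberate choice: without it, rows of the transition matrix become
infeasible at ages where $q_x h_s$ caps at 1 (every transition probability
would be negative once death claims the full row), whereas the conditioned
form is row-stochastic at every age and sends all living states to death
with probability 1 at the terminal age, where $q_x = 1$.

Per cycle the model accrues utility (QALYs), direct care costs, informal
care, productivity losses and — against the cycle's incremental deaths —
a human-capital lump sum for earnings foregone between the age at death
and retirement.

## Perspectives

The *healthcare* perspective counts direct medical spending: acute costs
plus annual mRS-dependent care. The *societal* perspective adds three
human-capital components: informal (uncompensated) care priced per mRS
state per year; productivity loss, `employment(age band) × (1 −
return-to-work(mRS)) × wage` below the retirement age; and foregone
earnings after premature death, attributed as a discounted lump sum at the
cycle of death. The death-year's earnings are counted in the lump sum
(not also as in-cycle productivity loss under the end-of-cycle
convention; under half-cycle correction up to half of that year can be
counted in both streams — a second-order effect we accept for
simplicity). Societal totals are by construction never below healthcare
totals.

## Parameters and their defaults

Values printed in the source data are used exactly: EVT procedure cost
15,510 USD; intravenous alteplase 7,421 USD; per-arm alteplase rates
0.621 / 0.558 / 0.585 (complete / accessible-2b / non-accessible-2b);
cohort start age 70. Costs carry an explicit `currency_year` and an
`inflation_factor` that `load_parameter_set()` applies to the cost fields
once, at load time, so a parameter file states its own price level.

Everything else — per-arm 90-day mRS distributions, utility weights
(0.95, 0.93, 0.83, 0.62, 0.42, 0.11 for mRS 0–5), mortality hazard ratios
(1.54–6.55), annual recurrence 4% with 15% case fatality, care and
informal-care cost ladders, wage and employment profiles — are synthetic
defaults in the range standard stroke cost-effectiveness analyses use.
They are internally consistent and produce the expected qualitative
behaviour (complete reperfusion dominant, the accessible incomplete
pattern worst off), but **absolute lifetime figures computed from them are
illustrative, not a replication**: the original analysis's full
point-estimate table is not redistributed with this package. Users with
access to trial-calibrated inputs should supply them through
`load_parameter_set()`; every downstream function is agnostic to where
the numbers came from.

Numerical conventions that matter, with defaults and rationale:

* **Discount rate** 3%/year on both costs and QALYs (US panel
  convention); configurable, including 0%.
* **Cycle correction**: half-cycle correction by default (accruals use
  the mean of the occupancy before and after the transition); an
  end-of-cycle mode (`"none"`) gives the exact expectation of a
  transition-at-cycle-start process and is what the microsimulation
  oracle and the closed-form checks use. The two modes shift lifetime
  QALYs by roughly ±0.2.
* **Horizon**: to the life-table maximum age (default 100), where the
  death probability is forced to 1, so "lifetime" is literal.
* **Recurrence worsening**: a pluggable matrix; the default truncates one
  arm-independent post-stroke distribution, avoiding invented per-state
  data.
* **Start age** 70 as a single representative cohort age; per-patient age
  mixtures can be explored by running the model over an age grid.
* **EVT passes** do not change the procedure cost: the multi-pass arm's
  costs flow entirely from its outcome distribution. (Its printed
  lifetime costs being *lower* than single-pass supports pricing EVT as
  one procedure.)

## Probabilistic sensitivity analysis

Every parameter carries a distribution: Dirichlet for the mRS vectors
(concentration = point estimate × effective sample size, set to the trial
arm sizes 506/147/296 where known), moment-matched beta for probabilities
and utilities, gamma for costs, lognormal for hazard ratios; 20% relative
standard error where no dispersion is reported (10% for utilities and
wages). `run_psa()` draws all parameters jointly, runs both arms on the
same draw (sharing one transition-matrix sequence), and reports
incremental costs and QALYs per draw; `acceptability()` is a brute-force
count of draws with positive incremental net monetary benefit at a
willingness-to-pay threshold (50,000 and 100,000 USD/QALY by default).

## Population scaling

`population_impact()` is deliberately plain arithmetic: a national annual
EVT volume, the fraction ending incomplete, the accessible split, and
per-patient deltas in, annual QALYs gained and savings out — exactly
linear in each input. The `"paper"` rounding mode rounds per-pattern
components before summing (QALYs to integers, savings to millions), which
is how such totals are conventionally printed; `"exact"` keeps full
precision.

## What the synthetic generators emulate — and what they do not

`generate_cohort()` draws arm membership, 90-day mRS, demographics and
IVT status from the configured multinomials, reproducing a trial-like
population's *margins* (including the 7/450 non-assessable angiograms) in
expectation. It does not model angiographic reading, covariate-outcome
correlation (age, NIHSS, ASPECTS do not influence mrs90), or within-site
clustering. `generate_life_table()` is a Gompertz law, not an actual
national table — smooth and monotone but without the infant/accident
structure of real tables (irrelevant at stroke ages).
`generate_parameter_table()` jitters the defaults while preserving the
validator's monotonicity constraints, giving property tests a family of
valid-but-different inputs. Consequently, passing tests demonstrate the
*mechanics* are right (conservation, dominance logic, oracle agreement,
published-arithmetic reproduction), not that the default inputs match any
particular trial population.

## Verification strategy

* Transition rows sum to 1 (within 1e-9) at every age for randomized
  parameter sets; death is absorbing and survival non-increasing.
* The cohort model agrees with an independent per-patient
  microsimulation (`microsim_oracle()`) within 3 standard errors on
  QALYs, both cost perspectives and life-years, under both cycle
  conventions.
* In the single-state constant-hazard limit the engine reproduces the
  geometric series $u(1-p)/p$ (end-of-cycle) and $u(1-p/2)/p$
  (half-cycle) to 1e-6 at horizon 1000.
* Dominance classification is checked exhaustively over the sign
  quadrants, and the net-monetary-benefit sign is verified against the
  dominance/ICER case analysis.
* Published arithmetic that is fully self-contained — the enrolment
  flowchart (1105/450/443/147/296, 33.2% accessible) and the national
  impact figures (14,275 QALYs; 129M/156M USD) — is reproduced exactly.

Problem sizes used by the default test run: microsimulations of 20,000
patients, PSA blocks of 100–10,000 draws, five randomized parameter sets
per property.

## Known limitations

Arm-level modelling only (no individual covariate effects); no
procedural-complication costing; the short-run phase is collapsed to the
90-day distribution rather than modelling acute events explicitly; the
recurrence-worsening rule is a structural assumption, not estimated; and
the default parameter table is synthetic where the source's supplementary
values are not public, so absolute cost and QALY levels should not be
quoted from the defaults.

## A worked run

```{r example, eval = FALSE}
ps <- default_parameter_set()
lt <- generate_life_table()
full <- run_lifetime("etici2c3", ps, lt)
acc <- run_lifetime("etici2b_accessible", ps, lt)
compare_arms(full, acc)
samples <- run_psa(ps, c("etici2c3", "etici2b_accessible"),
                   n_draws = 1000, master_seed = 1)
summary(samples)
population_impact(39000, 0.539, 0.332, c(1.14, 0.45), c(6188, 6156),
                  c(9317, 6473), "paper")
```
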