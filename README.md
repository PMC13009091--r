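# strokeCEA

Health-economic modelling of **reperfusion quality after endovascular
thrombectomy (EVT)** for large-vessel-occlusion ischemic stroke.

EVT often ends with *incomplete* reperfusion (final eTICI grade 2b rather
than 2c/3). Some of those patients retain a residual occlusion a
neurointerventionalist could still treat (EVT-accessible); others have
only small distal occlusions or slow flow (EVT-non-accessible, candidates
for intra-arterial pharmacological rescue). strokeCEA estimates what
converting incomplete patterns into complete reperfusion is worth: per
patient over a lifetime, and per year at national scale.

For whom: health-economics and outcomes researchers, stroke trialists and
methods reviewers who want a transparent, fully tested, scriptable
re-implementation of this class of decision model instead of a
proprietary modelling tool.

## The model

A two-phase Markov cohort model over seven health states — modified
Rankin Scale (mRS) grades 0–5 plus absorbing death:

1. **Short-run phase** (one 3-month cycle): each strategy arm is defined
   by its 90-day mRS distribution (mRS 6 → death); the cohort accrues a
   quarter-year of state utility and the acute costs (EVT 15,510 USD,
   expected intravenous alteplase 7,421 USD × arm IVT rate, other acute
   care).
2. **Long-run phase** (annual cycles to cohort extinction): from living
   state *s* at age *x*, death occurs with probability
   `1 − (1 − qx·hr_s)(1 − p_rec·cf)` (life-table mortality scaled by an
   mRS-specific hazard ratio, combined independently with fatal recurrent
   stroke), non-fatal recurrence deteriorates the state via a truncated
   post-stroke mRS distribution, and accruals are discounted at 3%/year
   with half-cycle correction (both configurable).

Costs run under a **healthcare** perspective (direct medical spending)
and a **societal** perspective adding informal care, productivity loss
(`employment(age) × (1 − return-to-work(mRS)) × wage`), and a
human-capital lump sum for earnings foregone by premature death. Arms are
compared by incremental cost-effectiveness ratio (ICER), dominance and
net monetary benefit; `run_psa()` adds second-order Monte Carlo
sensitivity analysis (Dirichlet mRS vectors, beta/gamma/lognormal scalar
parameters) with acceptability at 50,000 and 100,000 USD/QALY;
`population_impact()` scales per-patient increments to an annual national
EVT volume.

The packaged default parameter set uses published acute prices and IVT
rates verbatim; long-term inputs (utilities, hazard ratios, care-cost
ladders, arm mRS distributions) are documented synthetic stand-ins in the
standard range of the stroke CEA literature — see the methods vignette
(`vignettes/reperfusion-cea-methods.Rmd`) before quoting absolute
numbers. Supply calibrated inputs with `load_parameter_set()`.

## Worked example

```r
library(strokeCEA)
ps <- default_parameter_set()
lt <- generate_life_table()

full <- run_lifetime("etici2c3", ps, lt)          # complete reperfusion
acc  <- run_lifetime("etici2b_accessible", ps, lt) # incomplete, accessible
full
#> Lifetime outcome - etici2c3
#>   QALYs (discounted)               4.616
#>   life-years                       7.208
#>   cost, healthcare (USD)          107152
#>   cost, societal (USD)            156737
#>   discount 3.0%/yr, half_cycle correction, ages 70-100

compare_arms(full, acc)
#> Incremental analysis: etici2c3 vs etici2b_accessible
#>   incremental QALYs              1.225
#>   healthcare: saves cost 11481 USD, intervention dominant
#>   societal: saves cost 24427 USD, intervention dominant
```

Complete reperfusion yields ~1.2 extra discounted lifetime QALYs *and*
costs less from both perspectives, i.e. it is the dominant strategy (no
ICER is reported for a dominant strategy). Under parameter uncertainty
the conclusion is stable:

```r
s <- run_psa(ps, c("etici2c3", "etici2b_accessible"),
             n_draws = 1000, master_seed = 1)
summary(s)
#> PSA: etici2c3 vs etici2b_accessible - 1000 draws
#>   mean incremental QALYs     1.229
#>   mean incremental cost     -11696 (healthcare) /   -24962 (societal) USD
#>   acceptability @  50,000 USD/QALY (healthcare) 100.00%
#>   ...
```

Scaling published per-patient increments to the ~39,000 US EVT
procedures per year (53.9% incomplete, 33.2% of those accessible):

```r
population_impact(39000, 0.539, 0.332,
                  delta_qaly = c(1.14, 0.45),
                  delta_cost_healthcare = c(6188, 6156),
                  delta_cost_societal = c(9317, 6473),
                  rounding_mode = "paper")
#> Annual population impact (39,000 procedures/year, 53.9% incomplete)
#>   patterns: accessible / non-accessible / total
#>   patients converted       6979 / 14042 / 21021
#>   QALYs gained per year    7956 / 6319 / 14275
#>   healthcare savings (M$)  43 / 86 / 129
#>   societal savings (M$)    65 / 91 / 156
```

That is ~14,275 QALYs and ~129M USD (healthcare) / ~156M USD (societal)
potentially recoverable per year in the US.

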