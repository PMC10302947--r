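# htncea

Cost-utility modelling of hypertension prevention strategies with a
four-state Markov cohort model.

## The problem

Hypertension can be prevented population-wide (lifestyle modification for
everyone), in high-risk groups (prophylactic drugs above a blood-pressure
threshold), or in a personalized way (escalating bundles guided by an
individual risk score). Comparing these economically requires a model of
the *natural history* of blood pressure — including the possibility that
pre-hypertension regresses to normal — together with the downstream
complications that make hypertension expensive and deadly.

`htncea` is for health-economics modellers and methods researchers who
need such a model as transparent, tested, configuration-driven code. A
closed cohort moves annually between **normal → pre-hypertension →
stage I → stage II** (regression only from pre-hypertension back to
normal), faces state-specific annual hazards of **AMI, stroke and ESRD**
(independent within a cycle, so all seven complication combinations
arise), and dies of complications through immediate case fatality at the
event and a yearly mortality thereafter.

For strategies *S* versus comparator *C*, the model reports discounted
totals and the incremental cost-utility ratio

```
ICUR = (Cost_S − Cost_C) / (QALY_S − QALY_C),
```

net monetary benefit `NMB(λ) = λ·QALY − Cost`, cost-effectiveness-plane
quadrants, and — via Monte-Carlo sampling of every parameter's Beta or
Triangular uncertainty distribution — CE-plane scatters and
cost-effectiveness acceptability curves (CEACs). Intervention efficacy
enters as blood-pressure lowering converted to hazard ratios by the
log-linear relation `HR = 2^(−ΔSBP/20)`, mixed with all-or-nothing
compliance, and applied on the rate scale (`p' = 1 − (1−p)^HR`).
Personalization multiplies progression rates by `exp(score)` for a linear
covariate risk score.

Several inputs behind the published version of this model (transition
probabilities, prevalence, utility weights, risk-score coefficients) were
never made public; the bundled configuration carries documented
placeholder values flagged `assumption`, and every parameter's provenance
is tagged and auditable (`param_provenance()`).

## Worked example

```r
library(htncea)
ps <- load_parameters(htncea_example_config())
cea <- htn_cea(ps)
print(cea)
```

```
Cost-utility analysis (20-year horizon, 3.0%/yr discount, vs usual_care)
        strategy  cost    qaly increment_cost increment_qaly   icur     quadrant
      usual_care  2407 14.0118             NA             NA     NA         <NA>
 population_wide  8908 14.1120           6502         0.1002  64879 trade_off_ne
       high_risk  3203 14.0741            796         0.0623  12778 trade_off_ne
    personalized 16299 14.1180          13892         0.1062 130814 trade_off_ne
```

Each row is one strategy run on the same risk-stratified cohort:
discounted cost (USD/person) and QALYs over 20 years at 3%/yr, the
increments versus usual care, the ICUR (USD per QALY gained) and the
CE-plane quadrant. On the bundled *assumption* configuration all three
active strategies buy QALYs at a price (northeast quadrant) — these
numbers are regression fixtures for the pipeline, not reproductions of any
published totals, which depend on unpublished inputs.

```r
psa <- run_psa(ps, n = 200, seed = 1)
print(psa)
```

```
PSA: 200 replicates (seed 1), comparator usual_care
  population_wide: mean d_cost 4473 USD, mean d_qaly 0.3315, P(dominant) 0.00
  high_risk: mean d_cost -1307 USD, mean d_qaly 0.2989, P(dominant) 1.00
  personalized: mean d_cost 11273 USD, mean d_qaly 0.3723, P(dominant) 0.00
```

Under parameter uncertainty the high-risk strategy is dominant (cheaper
and more effective) in every replicate here, driven by the heavy sampled
ESRD burden of the published Beta distributions; `compute_ceac(psa)` turns
the same replicates into acceptability curves and `plot(psa)` /
`plot(ceac)` draw the CE plane and CEAC.

A command-line wrapper is installed as `exec/htncea` with subcommands
`validate`, `run`, `cea`, `psa` and `synth`; every output directory gets a
`manifest.json` and a `provenance.csv`.

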