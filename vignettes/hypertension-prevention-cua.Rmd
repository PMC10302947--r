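---
title: "A four-state Markov cost-utility model of hypertension prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-state Markov cost-utility model of hypertension prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htncea)
```

## The model

`htncea` implements a deterministic cohort state-transition model of the
natural history of hypertension and of four strategies for preventing it,
with a discounted cost-utility analysis on top and a Monte-Carlo
probabilistic sensitivity analysis (PSA) around it.

**Disease states.** A closed cohort moves annually between four
blood-pressure states: normal, pre-hypertension, stage I hypertension and
stage II hypertension. Progression is normal → pre → stage I → stage II;
the only regression permitted is pre-hypertension → normal, reflecting the
clinical observation that established hypertension does not spontaneously
remit while the pre-hypertensive state may. Stage II is absorbing within
the disease space. The annual transition matrix therefore has exactly four
free off-diagonal cells, and `build_transition_matrix()` completes each row
to 1 and rejects rows whose exit probabilities exceed 1.

**Complications and mortality.** Each year, every alive individual faces
state-specific annual probabilities of three end-organ complications:
acute myocardial infarction (AMI), stroke, and end-stage renal disease
(ESRD). Hazards act independently within a cycle, so joint events generate
the seven non-empty complication combinations (AMI, stroke, ESRD, and
their pairs and triple); acquired complications persist for life. An
incident event kills immediately with a complication-specific case
fatality; prevalent carriers face a complication-specific yearly mortality
thereafter. There is no background (other-cause) mortality: over a 20-year
horizon in a middle-aged cohort the complication-attributable deaths are
the quantity of interest, and an all-cause layer would affect all
strategies nearly equally; this is a known limitation for longer horizons.

ESRD deserves a note: its published mortality is a single annual figure
with no immediate/yearly split, and we model it entirely as a yearly
dialysis-era hazard (immediate mortality 0). This is a documented
assumption in the bundled configuration.

**Cycle accounting.** The within-cycle update order is (1) disease-state
transition, (2) complication events at the new state's hazards,
(3) immediate case fatality on incident events, (4) yearly mortality on
prevalent carriers. Costs and utilities are counted at cycle end, cycles
1..T; cycle 0 holds the initial distribution and carries zero flows. No
half-cycle correction is applied — the convention is the simplest auditable
one, it makes the full-utility cohort's discounted QALY total equal the
plain annuity $\sum_{t=1}^{T}(1+r)^{-t}$ exactly, and it is applied
identically to every strategy so incremental results are affected far less
than totals. Event costs (admissions) are charged to every incident event,
including those who die of it; maintenance costs (visits, the ESRD annual
cost) are charged to alive carriers from the event cycle onward; terminal
care is charged once in the cycle of a complication death; intervention
bundles are charged per offered person-year regardless of compliance.

**Utilities.** Each alive individual accrues the product of a
disease-state weight and the multipliers of any complications carried
(a `minimum` combination rule is available); dead contributes zero. No
utility weights were published for this model, so the bundled weights are
placeholder conventions flagged `assumption` — chosen once at values typical
of the health-state-utility literature (normal 1.00 down to stage II 0.90;
AMI 0.76, stroke 0.63, ESRD 0.59) and not revisited.

## Risk scores and personalization

The published model stratifies the population by state-specific risk
scores estimated from a community cohort whose coefficients are not
public. We adopt the standard multistate-regression convention: a linear
score $s = \beta_0 + \sum_i \beta_i x_i$ whose exponential multiplies the
progression *rates*. Probabilities are scaled on the rate scale,
$p' = 1-(1-p)^{e^{s}}$, which keeps them in $[0,1]$ for any multiplier —
naive multiplication would not. By default the regression probability
(pre → normal) is *not* modified by the score, since its covariate
dependence was never stated; `modify_regression = TRUE` scales it by
$e^{-s}$ instead.

The cohort is split into low/mid/high risk groups (score tertiles by
default, with representative group scores −0.5, 0, +0.5 and equal weights
in the bundled configuration). Every strategy is evaluated on the same
three-group mixture, so strategies are compared on an identical
heterogeneous cohort; only the *assignment rules* differ by group.

## Strategies, efficacy and compliance

Four strategies are configured:

* **usual care** — no preventive bundle; stage I/II pay routine
  hypertension management costs;
* **population-wide** — low-intensity lifestyle modification plus
  screening/awareness for every non-stage-II state, regardless of risk;
* **high-risk** — prophylactic drug plus education for stage I/II only
  (the classic threshold rule);
* **personalized** — escalating bundles by risk group: screening and
  low-cost lifestyle for the low group, mid-intensity lifestyle plus
  regular checkups for the mid group, full lifestyle plus prophylactic
  drug and advanced checkups for the high group.

Blood-pressure lowering per state (7 mm Hg systolic in pre-hypertension,
16 in stage I, 19.5 in stage II; the normal-state value mirrors the
pre-hypertension lifestyle effect and is flagged an assumption) converts
to a hazard ratio by the log-linear epidemiological relation
$HR = 2^{-\Delta SBP/20}$ — risk halves per 20 mm Hg of usual systolic
pressure. The diastolic figures are carried in the configuration but
unused. Screening and awareness cannot lower progression out of stage II
(which is absorbing anyway), but treatment efficacy still lowers stage II
complication hazards.

Compliance (lifestyle 60%, screening 70%, medication 50%) acts as an
all-or-nothing population mixture:
$HR_{\text{eff}} = c \cdot HR + (1-c)$. Each strategy rule carries one
compliance key; for the personalized high-risk bundle, which combines
lifestyle and drug, the medication compliance governs the whole rule (the
drug is the dominant component) — this is configurable per rule. Effective
hazard ratios from multiple applicable rules multiply, and are applied on
the rate scale like the risk score.

## Parameters, uncertainty and provenance

Every scalar input carries a base-case value, an optional uncertainty
distribution (Beta for probabilities, Triangular for costs and the
discount rate) and a provenance tag. The bundled configuration keeps the
published table literally: where a published base case and its Beta
distribution disagree (several ESRD rows), the base-case run uses the
printed value and the PSA samples the printed Beta. Where only a
distribution was published, the base case defaults to the triangular mode
(consistent with the 3% base-case discount rate, the mode — not the mean —
of its Triangular(0, 0.03, 0.05)) or the beta mean (consistent with every
beta row that has a printed base case). One published cost triple was
printed with its low and mode transposed (45, 40, 54) and ships sorted.
Two hazard presets are available, `table1` (default) and `section24`,
because the tabulated per-state complication hazards and the ones listed
in the source's running text differ; both are shipped rather than silently
reconciled.

Four kinds of input were never published and are required configuration
with documented placeholders flagged `assumption`: the four transition
probabilities (0.08, 0.06, 0.04 progression, 0.10 regression per year —
the scale reported for community screening cohorts), the initial state
distribution (45/35/15/5%), the utility weights (above) and the risk-model
weights. They were chosen once for plausibility and are not calibrated to
reproduce any published totals; consequently the package's base-case
costs, QALYs and ICURs on the bundled configuration are *regression
fixtures*, not reproductions.

PSA draws each distributed parameter independently per replicate
(replicate $r$ uses seed $\mathrm{xor}(\text{seed}, r)$, so runs are
reproducible and extensible), shares the sampled set across strategies
within a replicate (common random numbers, reducing the variance of
increments), and renormalizes the pre-hypertension row with a warning in
the rare event that its two sampled exit probabilities sum above 1. Beta
draws are always valid probabilities and triangular draws stay in their
support, so no other truncation is needed.

## Economics

Discounted totals are $\sum_t \text{flow}(t)\,(1+r)^{-t}$ with $r=3\%$ per
year by default. The incremental cost-utility ratio is
$\mathrm{ICUR} = \Delta C / \Delta E$ versus usual care (any comparator can
be configured); it is undefined at $\Delta E = 0$, negative ratios are
reported verbatim but flagged by the cost-effectiveness-plane quadrant
(`dominant` strictly cheaper and more effective; ties and the origin fall
in the northeast trade-off quadrant by convention), and reports round USD
to integers and QALYs to four decimals. Acceptability curves use net
monetary benefit $\lambda E - C$ on a WTP grid (0–300,000 USD/QALY by
10,000 by default); NMB ties count 0.5 so two-way curves sum to 1.

## The synthetic-data module

`generate_profiles()` draws covariate profiles (age, BMI normal; male,
smoker Bernoulli) with known weights, computes their scores and stratifies
them — it emulates the *structure* of a risk-stratified screening cohort,
not the joint covariate distribution of any real population, so passing
tests demonstrate correct score arithmetic and stratification, not
calibration to real risk factors. `generate_toy_model()` produces
parameter sets with closed-form behaviour (frozen cohort; a pure geometric
pre → stage I chain, occupancy $1-(1-p)^t$; a single-complication model
with first-cycle deaths $h\,m$) used by the oracle test suite.
`make_reference_run()` emits the deterministic comparison table on the
bundled configuration as a regression fixture.

## Problem sizes and numerics

The deterministic engine propagates a 4 × 8 occupancy array (disease ×
complication set) plus a dead compartment; mass conservation is asserted
every cycle at $10^{-9}$, and the engine matches two-state geometric
closed forms at $10^{-12}$. The test suite runs the full pipeline at small
PSA sizes (tens of replicates); the demo PSA in the acceptance script uses
1,000 replicates (about a minute on one core), and the package default is
10,000 (a few minutes). Monte-Carlo means are tested within four standard
errors of the closed-form distribution means.

## Known limitations

* No background mortality, no age structure, no treatment switching or
  adverse drug events.
* Utility weights, transition probabilities, prevalence and risk-model
  coefficients are placeholders; absolute costs/QALYs on the bundled
  configuration are not comparable to any published totals, although the
  comparison *arithmetic* (increments, ICURs, quadrants) is exact.
* Compliance is a static mixture, not an adherence process over time.
* Only three complications are modelled; peripheral arterial disease,
  retinopathy and heart failure are omitted, which biases against the
  prevention strategies.

## A worked run

```{r example, eval = FALSE}
ps <- load_parameters(htncea_example_config())
cea <- htn_cea(ps)
print(cea)

psa <- run_psa(ps, n = 1000, seed = 1)
ceac <- compute_ceac(psa)
plot(psa)
plot(ceac)
```
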