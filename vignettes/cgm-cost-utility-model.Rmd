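---
title: "A Markov cohort cost-utility model of continuous glucose monitoring in type 1 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of continuous glucose monitoring in type 1 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmcea)
```

## The decision problem

Adults with type 1 diabetes manage glycemia with intensive insulin therapy
guided either by finger-stick self-monitoring of blood glucose (SMBG) or by
continuous glucose monitoring (CGM). CGM lowers average hemoglobin A1c by
about 0.5 percentage points, which slows the development of long-term
complications, but the device costs several thousand dollars a year. The
question the model answers is whether, from a societal US perspective, that
trade is worth making: how many quality-adjusted life years (QALYs) does CGM
buy, at what incremental cost, and what is the incremental
cost-effectiveness ratio (ICER)?

`cgmcea` implements this as a deterministic two-arm Markov cohort model. A
cohort enters at age 40 with a 20-year history of diabetes and no
complications and is followed for 33 one-year cycles (to age 73, the design
life-expectancy anchor). Both arms share one state space of 13 states:

* diabetes with no complications;
* four first complications — retinopathy, nephropathy, neuropathy, coronary
  heart disease (CHD);
* three severe complications — blindness, end-stage renal disease (ESRD),
  lower-extremity amputation (LEA);
* four two-complication composites — nephropathy+CHD, neuropathy+CHD,
  retinopathy+CHD, neuropathy+nephropathy;
* death.

Composite states, blindness, ESRD and LEA are terminal apart from death:
patients who reach them stay until they die. Annual transition probabilities
are constant over time (no duration dependence). The three moves from CHD
into the composites reuse the corresponding microvascular-to-CHD
probabilities, reflecting the symmetry assumption under which those rates
were estimated.

The CGM arm differs from SMBG in exactly two ways:

1. **Device costs** — an initial cost ($4,809) in cycle 0 and an annual cost
   ($4,189) added to every living state from cycle 1 on.
2. **Risk reductions** — relative risk reductions for the incidence of
   retinopathy (0.306), nephropathy (0.270), neuropathy (0.188) and CHD
   (0.050), derived from the 0.5% A1c effect. Each reduction multiplies the
   probability of *every* transition whose destination adds that
   complication, wherever the patient starts (so the nephropathy reduction
   scales no-complications→nephropathy, neuropathy→neuropathy+nephropathy
   and CHD→nephropathy+CHD alike). Mortality is never reduced directly; CGM
   only delays entry into states that carry excess mortality.

## Rewards, discounting and outputs

Rewards accrue at the end of each cycle `t = 1..33` and are discounted by
`(1.03)^(-t)`; no half-cycle correction is applied. The only cycle-0 reward
is the CGM initial cost, undiscounted. Each living state earns its annual
cost — a base diabetes cost ($6,705) plus the state's marginal cost, with
composite states summing their components' marginals — and its EQ-5D utility
adjusted for aging (−0.0003 per year of age past 40, floored at 0; at the
end of cycle `t` the cohort is `t` years past the start age). Costs are 2007
US dollars. Per arm the engine reports discounted and undiscounted totals,
life-years, and the full occupancy trace; `compare_arms()` forms ΔC, ΔE, the
ICER (or a dominance flag when the signs make the ratio meaningless), and
`net_monetary_benefit()` evaluates `WTP × ΔE − ΔC`.

Within a cycle, death is resolved first — each living state's death
probability is the baseline all-cause probability at the current age times
the state's hazard multiplier, capped at 1 — then the complication
transitions enter with their tabulated values, and the self-transition
absorbs the remainder. A parameter set whose exits plus death exceed 1 in
any state at any age is rejected with an error naming the state and age
rather than silently renormalised.

Degenerate configurations are defined rather than forbidden: a horizon of 0
yields an empty trace and no rewards except the CGM initial cost, and a
discount rate of 0 makes discounted and undiscounted totals identical.

## The synthetic mortality schedule

The published analysis took age-specific all-cause death probabilities from
CDC life tables averaged over race and gender, with complication-specific
increased risks from the ETDRS follow-up studies, all in a supplementary
appendix that is not reproduced here. The package therefore ships a clearly
synthetic stand-in with the same shape:

* a Gompertz baseline `q(age) = 1 − exp(−a·e^{b·age})` with `b = 0.085`
  (a mortality doubling time of roughly 8 years, typical of adult all-cause
  tables), and
* hazard multipliers per state, defaulting to retinopathy 1.2, neuropathy
  1.5, blindness 1.3, nephropathy 2.0, CHD 2.5, LEA 3.0, ESRD 4.0, with
  composite states taking the maximum of their components (a conservative
  combination that avoids double-counting) and no-complications fixed at 1.

These multipliers are placeholders in the spirit of the ETDRS excess-risk
estimates, not published values; `read_mortality_csv()` loads a real
schedule whenever one is available, and every multiplier is overridable.

The level parameter `a` is not chosen directly: `calibrate_mortality()`
bisects `log a` until undiscounted life expectancy from age 40 hits a target
(default 73 years, matching the design anchor) within 0.1 years. Two anchors
are supported. The default, `anchor = "cohort"`, targets the SMBG cohort's
life expectancy under the full schedule, so the modelled cohort itself
averages 73 years. `anchor = "disease_free"` instead anchors the baseline
table (a complication-free cohort reaches 73) and lets the multipliers act
as excess risk on top, which yields a heavier baseline — close to actual US
all-cause tables — and a diseased cohort dying in its late 60s. We default
to the cohort anchor because the anchor age is stated for the modelled
population, but the choice is a genuine open question and both are exposed.
Calibration runs the cohort engine over the schedule's full age range
(40–105 by default; survivorship past 105 is under 0.1% at the calibrated
level, so the truncation is immaterial), and the returned range is trimmed
to ages where every state's exits plus death remain feasible.

## Parameter uncertainty

Each uncertain input is published as a mean with a 2.5–97.5% credible range.
For the probabilistic sensitivity analysis (PSA) these are turned into
sampling distributions in the conventional way: beta for probabilities,
utilities and risk reductions, gamma for costs. The default fit treats the
printed range as an approximately normal 95% interval, `sd = range/3.92`,
and matches moments; the fitted mean is exact by construction. For two
strongly right-skewed risk-reduction rows (nephropathy, 0.270 with range
0.006–0.768; neuropathy, 0.188 with range 0.004–0.593) the moment fit puts
the 2.5% quantile more than 80% away from the printed bound, so `fit_beta()`
detects any miss beyond 15% relative error and re-calibrates the beta
concentration numerically — the mean still held exact — bringing both
quantiles within 1% of the printed bounds. Gamma fits never need this; all
ten cost rows round-trip within 1% as plain moment fits.

Draws are independent across parameters (no correlation structure is
published). Composite-state *costs* are recomputed from the drawn cost
primitives via the summation rule, so a high CHD cost draw consistently
raises all three CHD composites; composite-state *utilities* are drawn from
their own rows, which carry their own published ranges. Mortality is not
varied: the schedule has no published uncertainty. Infeasible draws (exits
plus death exceeding 1 somewhere) are redrawn and counted, and the PSA
aborts if more than 1% of iterations need a redraw; in practice redraws are
essentially never triggered at the published ranges.

`run_psa()` requires an explicit seed and is bit-reproducible from it. The
summaries are the cost-effectiveness plane quadrant fractions (axis
convention: ΔC = 0 counts as north, ΔE = 0 belongs to neither east region;
the four quadrants partition every cloud exactly), the share of draws with
positive net monetary benefit at given thresholds, and the acceptability
curve over a threshold grid.

## Univariate sensitivity

`tornado()` perturbs each ranged parameter to mean × (1 ± 15%), holding all
others at their means, and ranks parameters by the spread in net monetary
benefit. The willingness-to-pay for the ranking defaults to $100,000/QALY —
the headline probabilistic threshold — and is configurable; the published
figure does not state which threshold it used. Beta-bounded quantities are
clipped to [0, 1] with a notice (utility of no complications × 1.5 would
exceed 1, for example), and fixed settings (start age, horizon, discount
rate, age slope) are never perturbed. `probe_icer()` applies a single ±50%
probe and returns the full incremental result. The repeat-amputation
probability ("subsequent LEA", 0.110) is modelled as a cost- and
utility-neutral self-loop within the LEA state — the annual LEA cost already
recurs, and nothing is published about an event cost — so it is a parameter
the engine never reads and its tornado spread is exactly 0.

## Verification

The test suite checks, among others:

* row-stochasticity of every transition matrix (1e−12) and conservation of
  the cohort trace (1e−9), with death occupancy non-decreasing;
* the null-effect equivalence — with all four risk reductions at 0 the arms'
  traces are identical and ΔC is exactly the discounted device stream
  weighted by survival;
* closed-form accrual in degenerate configurations (no exits, no deaths,
  zero discounting);
* distribution round-trips for every published row (exact means, quantiles
  within 15%);
* an independent individual-level microsimulation oracle: 200,000 state
  paths per arm sampled from the same transition matrices reproduce the
  cohort engine's discounted cost and QALYs within three standard errors;
* seed-reproducibility of the PSA and of every written report.

Default problem sizes (10,000 PSA iterations, 200,000 microsimulation paths)
keep the whole suite under a minute on one core.

## What the synthetic schedule does and does not show

Because the mortality appendix of the original analysis is unavailable, the
shipped base case runs on the calibrated synthetic schedule. The structural
properties above are insensitive to that substitution, and the tornado's
top-ranked parameter (the utility of diabetes with no complications) and the
southeast-quadrant share of the PSA cloud reproduce the published analysis.
The headline point estimates do not: under the synthetic schedule the model
yields ΔC ≈ $48.7k, ΔE ≈ 0.29 and an ICER near $169k/QALY, against the
published ΔC $23,552, ΔE 0.523 and $45,033/QALY. The gap is structural
rather than a matter of tuning: the discounted CGM device stream alone is
about $75k, so the published ΔC implies complication savings near $50k —
an occupancy shift roughly 1.7× larger than the printed risk reductions
produce in this 12-state topology — and the gap persists essentially
unchanged across mortality anchors, multiplier scales up to clinically
extreme values, and broader risk-reduction scopes (applying the
microvascular reductions to within-track severe progression moves the ICER
only to ≈ $132k). The published model's richer progression pathways (it let patients
accumulate more than two concurrent complications) and its actual life
tables are the likely sources. Conclusions that depend on the absolute ICER should
therefore be drawn only after loading a real mortality schedule via
`read_mortality_csv()`; comparative and structural analyses (rankings,
quadrant geometry, dominance reasoning, reproducibility) stand on their own.

## Worked example

```{r example, eval = FALSE}
sched <- calibrate_mortality()        # synthetic schedule, cohort LE 73
bc <- run_base_case(model_parameters(), sched)
bc
psa <- run_psa(default_parameter_table(), sched, n = 10000, seed = 1)
quadrant_fractions(psa, wtp = 50000)
ceac(psa, c(50000, 100000))
head(tornado(mortality = sched), 3)
```
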