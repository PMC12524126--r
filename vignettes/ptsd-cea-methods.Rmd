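---
title: "Methods: a Markov cohort cost-effectiveness model for PTSD therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for PTSD therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsdcea)
```

## The decision problem

`ptsdcea` compares treatment strategies for post-traumatic stress disorder —
adjunctive neurofeedback delivered alongside usual therapy (NF + OT),
trauma-focused psychotherapy, and pharmacotherapy — on direct medical cost
and quality-adjusted life years (QALYs) over a three-year horizon, from a
US health-system perspective in 2023 USD. The core is a cohort
state-transition (Markov) model with quarterly cycles (12 cycles in the
base case).

Severity is carried as CAPS-5 bands: severe (60–80), moderate (40–59),
mild (20–39) and asymptomatic (0–19). The instrument only defines the three
symptomatic bands; the asymptomatic band is taken to be the remaining
contiguous range 0–19. A health state combines the current band with a
treatment status and with the band at model entry:

* `on_<band>_from_<entry>` — in therapy; improvement can move the patient
  one band milder per cycle, so the current band is never more severe than
  the entry band (6 states);
* `dropped_<band>` — out of therapy, frozen at the band held at dropout
  (3 states);
* `asymptomatic` — absorbing apart from background death;
* `dead` — absorbing.

Tracking the entry band is what lets a relapse "return the patient to their
original condition" without expanding the state space per patient.

## Cycle dynamics

Within each quarterly cycle, competing risks are composed multiplicatively
in a fixed order, each conditional on the previous events not occurring:

1. **death**, with a band-specific quarterly probability;
2. **dropout**, to the dropped state at the current band;
3. **relapse**, returning the patient to the entry band — with probability
   `retreatment_prob` they re-enter therapy there, otherwise they are
   counted as dropped at the entry band;
4. **improvement**, crossing into the next milder band (mild crosses into
   the absorbing asymptomatic state).

Mortality-first is the standard convention; the remaining order follows the
clinical narrative (a patient who leaves therapy this quarter no longer
benefits from it). Each row's residual mass stays in place, so rows sum to
one by construction (checked to 1e-12).

### Rate timescales

Published dropout and relapse figures for these therapies are
trial-duration quantities — the trials behind them run roughly 8–13 weeks,
about one model cycle — so the shipped base cases apply the printed rates
directly as quarterly transition probabilities
(`course_cycles = relapse_cycles = 1`). This also keeps the one-way
threshold analyses on the same scale as the published threshold tables.
Rates quoted on longer horizons can declare it per strategy; the engine
then rescales with the constant-hazard map
`per_cycle_prob(p, c) = 1 - (1 - p)^(1/c)`, whose inverse property
(applying the per-cycle probability `c` times recovers `p`) is tested
exactly.

### The improvement step

Improvement is driven by the strategy's CAPS-5 score-reduction
distribution. A patient in band `[lo, hi]` is assumed uniformly distributed
within the band; one course reduces the score by `max(N(mean, sd), 0)` —
a Normal draw censored at zero, since a therapy course is not allowed to
worsen the score. The band-crossing probability has the closed form

$$
P(\text{cross}) = \frac{\sigma}{w}\left[G\!\left(\frac{\mu}{\sigma}\right)
 - G\!\left(\frac{\mu - w}{\sigma}\right)\right],
\qquad G(z) = z\,\Phi(z) + \phi(z),
$$

with `w = hi - lo` the band width, degenerating to `min(max(μ, 0)/w, 1)`
as `σ → 0`. Censoring (rather than renormalised truncation) is what makes
this the plain Normal tail integral; the tests compare the closed form to a
deterministic quadrature oracle at 1e-6 and a 10^7-draw Monte Carlo oracle
at 3 standard errors. The probability is monotone non-decreasing in the
mean effect, which propagates into the engine-level property that a larger
effect never lowers total QALYs.

## Costs, utilities, discounting

Each symptomatic band carries a quarterly non-therapy care cost
(severe 5880, moderate 4900, mild 3450 USD; asymptomatic 0). Therapy cost
is a discrete course — 13.5 sessions at the Medicare per-session rate
(psychotherapy 147 → 1985 USD, NF + psychotherapy 140 → 1890 USD) — billed
once, spread over the course's cycles, while annual drug cost
(pharmacotherapy 1415 USD/yr) is billed every on-treatment cycle at the
cycle-length share. The once-billing base case reflects the published cost
table, which prices these therapies as a course total; a config flag
(`bill_therapy_every_cycle`) switches to re-billing the course every
on-treatment cycle. In once-billing mode, retreatment courses after relapse
are not re-billed — a small-mass simplification listed under limitations.

Utilities come from a linear CAPS-5 → EQ-VAS regression,
`EQ-VAS = intercept + slope × CAPS-5` clamped to [0, 100], evaluated at the
band midpoint and divided by 100. The default coefficients
(intercept 92, slope −0.68) place the asymptomatic midpoint near full
health (0.855) and the severe midpoint at 0.444, consistent with published
PTSD utility gradients; they are fully configurable because comparative
results depend on utility differences rather than absolute levels.
`normalize_effect()` additionally reweights a pooled effect between
subgroup mixes (military vs. civilian trial composition), solving the
subgroup effects from the pooling identity when only a pooled mean and an
effect ratio are known.

Costs and QALYs are valued at start-of-cycle occupancy (a half-cycle
correction flag averages start and end) and discounted at 3% annually:
`(1 + r)^(-t × cycle_length)`. A zero rate reproduces the undiscounted
totals exactly, and cumulative streams are reported at each whole year.

Background mortality defaults to a quarterly probability of 0.0005 (ages
40–45) scaled by hazard multipliers 1.0/1.3/1.6/2.0 for
asymptomatic/mild/moderate/severe; the cohort enters in equal thirds
severe/moderate/mild. Neither quantity is published for this model, so both
are configurable scenario fields with these defaults chosen once as
field-plausible values.

## Uncertainty analysis

**Probabilistic sensitivity analysis** samples every entry of the
scenario's `psa_distributions` — beta for probabilities, gamma for costs,
normal for effect means, built by method of moments from a mean and SD (or
a 95% CI width, converted as width/3.92) — runs both strategies per draw,
and classifies each (ΔCost, ΔQALY) pair on the incremental
cost-effectiveness plane. Dominance requires strictly lower cost and
strictly higher effect; a draw with ΔQALY exactly zero can be "cheaper"
but never "dominant". Where the sources print no dispersion, a 20%
relative SD is assumed; printed ranges (psychotherapy dropout 17.2–24%,
retreatment 20–80%) are read as 95% intervals. Sampled probabilities
outside [0, 1] are resampled, and a resample rate above 1% aborts the run
as evidence of a misspecified distribution. The acceptability curve
reports `P(wtp × ΔE − ΔC > 0)` over a willingness-to-pay grid; at the
base-case threshold of 0 USD/QALY this is exactly the probability of being
cheaper.

**Deterministic sensitivity** sweeps one dotted parameter path at a time
(`one_way`), ranks endpoint influence on incremental cost (`tornado`), and
solves break-even parameter values by bisection on the incremental
discounted cost (`find_threshold`), validated in the tests against a
10,000-point grid scan.

## The microsimulation oracle

`microsim()` replays the identical per-cycle probabilities and event order
patient-by-patient, realising the improvement step with continuous scores:
each cycle draws a fresh uniform within-band score and a censored Normal
effect, crossing when the treated score falls below the band's lower
bound. Treating the within-band score as exchangeable across cycles is
exactly the uniform-within-band assumption of the cohort engine's crossing
probability, so the two layers are consistent by construction and the
cohort trace must agree with the microsimulation mean to binomial error —
the tests require 3 SE per state per cycle at n = 50,000, and 2 SE in
aggregate at n = 200,000 for the degenerate midpoint/sd→0 case. For
multi-cycle courses the per-course crossing indicator is thinned to the
per-cycle scale so the two layers still match. All draws follow a fixed
per-cycle schedule from a single seed, giving bit-identical reruns and
common random numbers across strategies.

This consistency is deliberate: the microsimulation validates the cohort
algebra (matrix composition, accrual, discounting), not the band
abstraction itself. A score-persistent individual model — where a
patient's within-band position carries over between cycles — would drift
from the band model and is out of scope.

## Worked example

```{r example, eval = FALSE}
sc <- example_scenario("nf_vs_psychotherapy")
report <- run_comparison(sc, psa_n = 10000, seed = 1)
report
report$thresholds
```

## Problem sizes and numerical choices

The shipped analyses use 12 quarterly cycles, 10,000 PSA iterations
(matching the published simulation size), 50,000-patient microsimulation
checks, and bisection to |ΔC| < 0.01 USD for thresholds. Trace
conservation is enforced at 1e-9 per cycle, transition rows at 1e-12, and
method-of-moments inversions at 1e-10 relative error. Ties at quadrant
boundaries fall to the trade-off classes; the ICER is reported as
undefined (not ±∞) when ΔQALY is zero.

## Limitations

* The model reproduces the published comparative *directions* from printed
  inputs; exact magnitudes depend on appendix-only inputs (the full
  variable/distribution tables, the regression coefficients, the initial
  severity mix, state-specific mortality) and are not expected to match to
  the dollar. With the shipped defaults, the NF-vs-pharmacotherapy
  comparison is approximately cost-neutral at year 1 (within ~0.2% of
  year-1 spending) and clearly cost-saving from year 2.
* Dropped-out patients freeze at their dropout band; no spontaneous
  remission or deterioration is modelled.
* Retreatment courses are not re-billed under once-billing.
* No patient-level covariates (age, sex, military status) beyond the
  effect-level mix adjustment; no lifetime extrapolation beyond 3 years;
  no societal-perspective costs.
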