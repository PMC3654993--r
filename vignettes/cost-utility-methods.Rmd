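---
title: "Methods: a Markov cohort cost-utility model of antidepressant therapy in MDD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model of antidepressant therapy in MDD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcea)
```

## The model

`adcea` implements a cohort state-transition model of major depressive
disorder (MDD) built for cost-utility comparison of antidepressants. The
clinical course is described by six health states — depressive episode on
treatment, remission on treatment, depressive episode off treatment,
remission off treatment, well, and dead — on a monthly cycle. A cohort
enters the model in the on-treatment depressive episode at a mean age of
45 years and is followed for 24 cycles.

Two duration rules do not fit a memoryless chain directly, so remission is
expanded into six monthly *tunnel states*:

* a patient must spend six consecutive months in remission before moving
  to the well state, and
* the relapse hazard depends on time since entering remission (a Weibull
  curve), which the tunnel index carries; the clock resets on every new
  remission entry.

The expanded space has 16 states (`state_space()`). Per cycle, events
compose as follows:

1. **Death first.** The monthly background probability comes from the
   annual life table via `annual_to_monthly_prob()`. In the two episode
   states it is multiplied on the rate scale
   (`1 - (1 - q)^rr`) by the excess-mortality factor 20.35 reflecting
   suicide risk.
2. **Episode on treatment.** Surviving mass remits with the arm's monthly
   remission probability and discontinues with its monthly
   discontinuation probability, composed multiplicatively:
   remit-only mass enters the remission tunnel, discontinue-only mass
   moves to the off-treatment episode, and the both-events mass is routed
   "remit, then discontinue" into off-treatment remission. The published
   description gives only marginal monthly probabilities; this composition
   keeps rows stochastic and is pinned by a named constant and a test. The
   alternative routing (both-events mass staying on treatment) is not
   decidable from the description.
3. **Remission on treatment (tunnel month m).** Relapse occurs at the
   arm's conditional Weibull probability `1 - S(m)/S(m-1)`; because a
   relapsing patient always resumes the original treatment, relapse takes
   precedence, and only the non-relapsing mass may discontinue (keeping
   its tunnel month, off treatment). The remainder advances one tunnel
   month, exiting to well after month six.
4. **Off treatment.** The episode off treatment remits at a configurable
   untreated remission probability; off-treatment remission relapses along
   the placebo curve; there is no discontinuation off treatment. Relapse
   off treatment and recurrence from well both return the patient to the
   on-treatment episode.
5. **Well.** Recurrence at the monthly equivalent of the annual 20%
   recurrence probability. Dead is absorbing.

Relative risks of relapse versus placebo (fluoxetine 0.513, sertraline
0.633, escitalopram 0.531) act on the rate scale via `apply_rr_to_prob()`,
`1 - (1 - p)^rr`, which stays in [0, 1] for any positive relative risk and
differs from naive multiplication by O(p²).

## Accrual and economics

Accrual is at cycle end with no half-cycle correction (the source analysis
describes none). QALYs accrue as occupancy × utility / 12 with state
utilities 0.86 (well), 0.81 (remission) and 0.57 (episode). Expected
adverse-drug-reaction (ADR) disutility — Σ monthly frequency × decrement —
is subtracted from the state utility in on-treatment states; the
sleep-disorder term counts only in the episode state, since sleep
disturbance during remission is attributed to the depression rather than
the drug. Discontinuation symptoms are a one-time event applied to the
cycle's flow into off-treatment states: disutility 0.065 (set equal to
nausea) for one week, and a €52 management cost, both weighted by the
arm's symptom probability.

Cost streams per cycle: state direct costs (€190 episode, €35 remission
per month), indirect productivity costs (€380 / €173, included only under
the societal perspective), medication (standard price in the first cycle,
uplifted by the double-dose fraction thereafter), expected ADR management
costs, and hepatic monitoring for agomelatine (€75 per test at treatment
months 1, 2, 3 and 6 — weeks 3, 6, 12 and 24 mapped to months — weighted
by on-treatment occupancy and not re-billed after relapse within the
horizon). Costs and outcomes beyond the first year are discounted at 3.5%
per year pro rata: `discount_factor()` is 1 through cycle 12 and
`1.035^-((cycle-12)/12)` after.

Pairwise comparison (`incremental_analysis()`) reports incremental cost
and QALYs, a dominance label (dominant = cheaper and more effective), the
ICER ΔC/ΔQ when both increments share a sign, and net monetary benefit
λ·ΔQ − ΔC at thresholds of €40,000, €50,000 and €60,000 per QALY (the last
being three times per-capita GDP). Full-precision ratios are reported;
printed two-figure increments elsewhere can imply slightly different
rounded ratios.

## Parameters the published analysis leaves unspecified

Several inputs of the original analysis live in unavailable supplements.
They are explicit configuration entries with package defaults, chosen once
and documented here:

* **Life table.** A Gompertz hazard `h(x) = a·e^{bx}` with `a = 2e-5`,
  `b = 0.1` stands in for the national table; it gives adult mortality of
  realistic order (≈0.002/yr at 45, ≈0.015/yr at 65) and is monotone in
  age. `gompertz_life_table()` generates it; any table can be supplied via
  CSV (`age,annual_death_prob`).
* **Relapse curves.** The fitted Weibull parameters are unpublished. The
  defaults are exponential (shape 1) curves anchored at six-month
  relapse-free survival of 0.78 on treatment and 0.53 on placebo — the
  approximate six-month relapse fractions (≈22% and ≈47%) reported by the
  relapse-prevention trial the curve was fitted to. Shape 1 is an explicit
  assumption: no claim of increasing or decreasing hazard is made.
  `fit_weibull()` recovers shape/scale from any digitised survival points
  if better data are available.
* **Off-treatment course.** The untreated monthly remission probability
  (0.20) and the use of the placebo relapse curve off treatment are
  assumptions; both are ordinary config fields.
* **Escitalopram discontinuation symptoms.** Stored as the tabulated
  0.07 even though the surrounding text sets untabulated comparators to
  zero; tables are treated as authoritative for inputs.

Because of these stand-ins, the packaged base case reproduces the
published cost-effectiveness *regime* qualitatively (all QALY increments
favour agomelatine; dominance or low ICERs against the SSRI comparators;
see the acceptance test's printed calibration demonstration) but not the
published totals digit-for-digit, and the test suite asserts only the
former. The quantities that are exactly reproducible from printed inputs —
the expected ADR disutilities and the incremental costs implied by the
printed per-arm totals — are asserted exactly.

## Sensitivity analyses

**Deterministic (one-way).** `run_dsa()` re-runs a pairwise comparison at
the low and high extreme of each parameter. The published analysis used
"extreme values" without listing ranges, so the default grid
(`default_dsa_grid()`) varies each driver by ±20% clamped to its bounds;
any grid can be supplied. Entries are sorted by the net-monetary-benefit
span at the reference threshold (tornado order). Named scenarios
(`run_scenario()`) cover the payer perspective, exclusion of ADRs, sleep
disorder or discontinuation, and a one-year horizon; transforms compose.
`breakeven_remission()` bisects the comparator's remission probability for
the dominance boundary (ΔQ ≤ 0 and ΔC ≥ 0) rather than an ICER threshold,
matching the published framing of the break-even ("agomelatine is
dominated"). The published break-even rates (50.3% venlafaxine, 54.4%
escitalopram) depend on the unpublished relapse/mortality inputs and are
treated as qualitative reference points, not assertions.

**Probabilistic.** `run_psa()` performs second-order Monte Carlo:
probabilities and utilities draw from beta distributions, relative risks
and costs from lognormals, parameterised by method of moments
(`moment_match()`), with the standard deviation set to 10% of the mean
where no published variance exists (that is, everywhere in the default
configuration). Zero-valued means (e.g. agomelatine's
discontinuation-symptom probability) are fixed point masses, as are the
Weibull shape/scale (neither probabilities nor costs/RRs, the two families
assigned). Parameters are drawn independently — no correlation structure
is described — and one shared draw per iteration serves all arms, so
common inputs move together and do not add spurious incremental noise.
Draws failing validation are redrawn rather than truncated (truncation
would bias moments); the redraw count is recorded and a rate above 1%
warns. `ceac()` recounts draws into acceptability curves;
`bootstrap_summary()` gives percentile intervals of mean increments.
Because the distribution parameters of the original probabilistic analysis
are unpublished, the published dominance percentages (44.5%, 89.6%, 70.6%,
84.6% against branded comparators) are reproduction goals in sign and
ordering only, not magnitude.

## Numerical and testing choices

* Transition rows must sum to 1 within 1e−9 (asserted inside the engine);
  occupancy conservation is property-tested over 100 random
  configurations from `random_scenario()`, which draws structurally valid
  parameter sets inside documented ranges.
* Disutility never drives a state utility negative: clamped at zero with
  a warning.
* The engine is cross-checked against an independently written
  individual-level microsimulation of the same transition rules (200,000
  patients, fixed seed), agreeing within Monte Carlo error, and against a
  hand-computed three-cycle forward calculation to 1e−9.
* A degenerate identity pins accrual arithmetic: zero mortality, uniform
  utility *u*, no event burden and no discounting give exactly
  *u*·horizon/12 QALYs.
* Zero-variance PSA reproduces the base case bitwise; CEAC points equal
  brute-force recounts of the stored draws.
* Weibull fitting uses the linearised least-squares form
  ln(−ln S) = k·ln t − k·ln λ; it recovers noiseless parameters to 1e−9
  and stays within 10% under 1% multiplicative noise at n = 12.
* Test problem sizes (e.g. PSA runs of 8–120 iterations in unit tests,
  one 200,000-patient microsimulation, 10⁶ draws for the moment checks)
  were chosen to exercise each property at comfortable Monte Carlo
  resolution while keeping the default suite quick.
* YAML serialization writes doubles at 22 significant digits, making the
  save/load round trip bit-exact.

## Known limitations

The synthetic generators emulate structure, not history: the Gompertz
life table is not the national table, the relapse anchors are two-point
summaries of a trial rather than its full survival curve, and resource-use
micro-detail behind the state costs is collapsed into the two printed
monthly figures. Passing tests therefore demonstrate correctness of the
machinery and faithfulness to the printed inputs, not agreement with
unpublished data. The model has no age-dependent utilities, no efficiency
frontier across more than two arms, no correlation structure in the PSA,
and treats hepatic monitoring as non-recurring within the horizon.
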