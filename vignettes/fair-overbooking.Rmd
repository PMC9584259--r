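---
title: "Fair predictive overbooking: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fair predictive overbooking: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Outpatient clinics lose provider time to no-shows, and the standard
counter-measure is *predictive overbooking*: a machine-learning model
predicts each patient's probability of showing up, and an optimizer books
more than one patient into some slots, preferentially the patients least
likely to come. Because attendance correlates with socio-economic
circumstance, and socio-economic circumstance correlates with race in US
clinic data, the patients placed in overbooked slots — and in the slot
right after one, where delays spill over — belong disproportionately to
one ethno-racial group. Those slots carry systematically longer waits, so
an accurate model plus an efficiency-only optimizer reproduces a racial
wait-time disparity.

`fairbook` implements this pipeline with the prediction stage and the
optimization stage *decoupled*, so that each can be intervened on
independently: drop the model entirely, drop only the socio-economic
features, keep the model but make the objective group-aware, or keep the
model and make the objective min-max over individuals without reading
group labels. An exact evaluator, disparity metrics, and a synthetic
population generator make the whole comparison reproducible at desk
scale.

# The clinic-day model

A session has `n_slots` equally spaced slots of `slot_duration` minutes
(defaults: 10 slots of 30 minutes). An assignment books every rostered
patient into exactly one slot, at most `capacity` (default 2) per slot.
Given a show/no-show realization, the day unfolds deterministically:

* shown patients are served in (slot, within-slot priority) order;
* each service takes exactly one slot duration;
* a patient's service starts at the later of their slot start and the
  provider becoming free; their wait is the difference;
* no-shows wait zero and consume no provider time;
* idle time is the provider's non-serving time up to the later of session
  end and last completion, and overtime is any serving past session end.

Deterministic unit services are an explicit modeling choice: they make
the knock-on arithmetic exact (a double-booked slot delays its second
patient by exactly one slot length, and that delay propagates until a gap
absorbs it) and they are what the within-package expectations enumerate.
Stochastic service times and late arrivals are out of scope; lateness is
folded into no-show behaviour. Patients arrive punctually at their slot
start. All internal times are minutes from session start, so the
recursion is exact in integer arithmetic whenever the slot duration is an
integer.

Within-slot priority defaults to roster order and is never derived from
group labels; it is configurable because nothing in the day model itself
dictates who of two double-booked patients is served first.

**Expected outcomes.** For show probabilities $p_1,\dots,p_n$ the
evaluator enumerates all $2^n$ show vectors, runs the recursion on each,
and weights by $\prod_i p_i^{s_i}(1-p_i)^{1-s_i}$. Enumeration is exact
up to a cutoff of 20 patients (about a million outcomes); beyond it a
seeded Monte-Carlo estimator with common random numbers takes over
(default 10,000 samples for reporting, 2,000 inside the optimizer). The
hot loop lives in C++; an independent plain-R reference implementation in
the test suite cross-checks it.

**Schedule cost.** The scalar objective of the traditional method is

$$C = w_w \sum_i E[\text{wait}_i] + w_d\, E[\text{idle}] +
w_o\, E[\text{overtime}],$$

with default weights $(1,1,1)$ weighted minutes. The original study's
weight vector is unpublished, so all cost-level comparisons here are
weight-relative; the weights are configurable and logged with every run.
Schedule *quality* is simply the negation of schedule cost — no separate
scale is invented.

# The synthetic population

No deposited clinic dataset exists for this problem, so the generator
emulates the asserted structure: a binary group label (`B`, 30%, vs
`nonB`, 70%), three socio-economic features shifted between groups, and a
latent show probability that is a logistic function of the SES features
*only*. Group therefore influences attendance exclusively through its
correlated features — proxy structure emerges rather than being injected
— and a logistic refit with the group label added recovers a group
coefficient statistically indistinguishable from zero (tested).

Defaults, chosen once as plausible clinic magnitudes:

| parameter | nonB | B |
|---|---|---|
| income index | N(0, 1) | N(-1.5, 1) |
| employed | 0.90 | 0.70 |
| married | 0.55 | 0.40 |

with show-model coefficients (intercept 0.95; income 0.5; employment 0.8;
marriage 0.3). By numerical integration these imply mean show
probabilities of about 0.85 (nonB) and 0.69 (B) — the roughly 0.15-margin
regime — and an overall show rate near 0.80, in the range clinics report.
Each patient also receives an attendance history of 8 prior visits drawn
i.i.d. from their latent probability; histories of this length make the
history-only model informative but clearly noisier than the full model,
which is the regime in which feature-dropping interventions are
interesting at all.

What the generator does *not* emulate: temporal drift, feature
measurement error, correlated attendance within households or over time,
more than two groups, and any direct dependence of attendance on group
after conditioning on features. Passing benchmarks on this population
therefore demonstrates the mechanics of proxy discrimination and of the
interventions, not magnitudes for any real clinic.

# Show-probability models

Three regimes mirror the intervention menu on the prediction stage:

* **FULL** — logistic regression of per-visit attendance on all SES
  features plus two history summaries (past shows, past visits). Summaries
  are computed causally in the training table (a visit sees only earlier
  visits).
* **NO_SES** — the same fit with SES features excluded; predictions are
  exactly invariant to SES values (tested by permutation).
* **NONE** — no model; every patient receives the overall mean show rate
  of the history.

Plain unregularized logistic regression is deliberate: it is the minimal
model producing individual show probabilities, and on the generator's
population it is correctly specified, so the FULL fit recovers the
generating coefficients (with true zero loadings on the history
summaries, since attendance is independent of history given SES). Day-of
-week or other calendar features are accepted if present but not
required.

# Objectives and constraints

Three objective variants share the idle and overtime terms and differ in
the wait term:

* **TRADITIONAL** — total expected wait (the schedule cost above);
* **RACE_AWARE** — $n \times$ the largest *group mean* show-conditional
  expected wait, so the optimizer minimizes the waiting of the group
  expected to wait longer. Requires group labels.
* **RACE_UNAWARE** — $n \times$ the largest *individual*
  show-conditional expected wait; group labels are never read.

Two compositions here were genuinely open and are package decisions.
First, the fair variants retain the idle/overtime terms — only the wait
term is redefined — so clinic-efficiency pressure is preserved and the
variants stay comparable under one weight vector; the $n$ scaling keeps
the min-max wait term in total-wait units. Second, the fair wait terms
use *show-conditional* expected waits $E[\text{wait}]/p_i$ rather than
unconditional ones. The conditional form is what clinic wait-time records
measure (only patients who come wait), and it is the form under which
treating everyone identically actually produces zero disparity: on the
unconditional scale a group's lower show rate mechanically deflates its
mean wait, which both biases the min-max objectives and produces a large
spurious negative "disparity" for a completely group-blind scheduler.
The traditional cost keeps the unconditional total, which is the correct
efficiency aggregate. The disparity metric accepts
`conditional = FALSE` for the unconditional variant.

**Quota constraints** restrict feasible schedules via *desirable slots* —
slots neither overbooked nor immediately following an overbooked slot.
A group quota demands a minimum fraction of desirable slots per group
(e.g. at least 20% to group B and 60% to nonB on a 30/70 roster); a risk
quota, its group-blind analogue, reserves a minimum fraction for patients
whose predicted no-show risk is in the top third of the roster (tercile
boundaries computed on the current roster, ties resolved by patient id).
When no slot is desirable the fractions are undefined and the constraint
is reported unsatisfied. Statistical parity itself is exposed as a metric,
not as a hard constraint.

# Optimizers

`optimize_oracle()` enumerates every capacity-feasible assignment (with
within-slot priority canonicalized to roster order), filters by
constraints, and returns the exact minimizer; ties break lexicographically
on the roster-ordered slot encoding, which is group-blind by
construction. It is limited to 7 patients and 5 slots and serves as the
correctness reference.

`optimize_heuristic()` scales beyond that: a greedy start (patients in
decreasing predicted show probability get one slot each; the overbooked
remainder is placed cost-minimally) improved by first-improvement local
search over single-patient moves, pairwise swaps, and whole-slot content
swaps, with seeded random restarts (default 20). Two numerical details
matter. Min-max objectives are piecewise flat, so moves that leave the
objective unchanged but lower the traditional cost are accepted — a
lexicographic tie-break that walks plateaus instead of stalling on them.
And quota constraints are handled by a large feasibility penalty during
search with a hard feasibility check on the result; an infeasible model
raises an error naming the binding quota rather than returning a
violating schedule. On a 990-run audit of random instances with up to 6
patients and 4 slots the heuristic matched the oracle's objective on
every instance and variant.

# Fairness metrics

* **Wait-time disparity**: signed percent difference between the two
  groups' mean (show-conditional) expected waits, with the *average of
  the two group means* as denominator — a symmetric choice that stays
  finite when one group barely waits. The original reports only "percent
  difference"; the other-group mean and the overall mean are available as
  alternative denominators. Zero by convention when nobody ever waits.
* **Statistical-parity gap**: $P(\text{wait} > t \mid B, \text{shown}) -
  P(\text{wait} > t \mid \text{nonB}, \text{shown})$, computed over the
  exact show-vector distribution (Monte Carlo above the enumeration
  cutoff). Default threshold $t = 0$: any wait at all.
* **Optimality gap**: percent excess of a method's schedule cost over a
  reference cost, conventionally the cost-minimizing method on the same
  instances.

# The benchmark harness

`run_comparison()` replays the four interventions against the
state-of-the-art baseline over replicated clinic days:

* **SOTA** = FULL model + TRADITIONAL; **NO_ML** = NONE + TRADITIONAL;
  **NO_SES** = NO_SES + TRADITIONAL; **RACE_AWARE** = FULL + RACE_AWARE;
  **RACE_UNAWARE** = FULL + RACE_UNAWARE.

Show models are fit once per run on a training population (default 2,000
patients) from the same generator and applied to every day — fitting a
logistic model per 12-patient day would be statistically meaningless.
Each replicated day draws a fresh roster (cross-sectional replication;
the comparison is between schedules, not clinic dynamics), optimizes
under each method's predictions and objective, and then evaluates the
chosen schedule's expected outcome under the *generator's latent* show
probabilities — so prediction error surfaces as realized cost, and the
per-day optimality gap against SOTA reflects genuine efficiency loss.
Days where the roster happens to contain a single group contribute no
disparity observation.

Disparity is aggregated across days as a *ratio of averages*: the percent
difference between the day-averaged group mean waits, with a
leave-one-day-out jackknife standard error. The alternative — averaging
per-day percent differences — is badly biased on 12-patient rosters: the
per-day ratio is bounded at ±200% and saturates at the negative bound on
every day in which the 30% group happens to draw no delayed patient, so
even a provably group-blind scheduler averages around −25% on that
scale. The per-day values are still reported in the day-level table for
inspection; the summary uses the pooled form, which is also how a study
would compute "average wait of group B vs non-B" from test-set data.

Default problem size: 10 slots × 12 patients at capacity 2 (two forced
overbooks, exact $2^{12}$ evaluation), 200 replicated days, heuristic
budget of one restart per day. These sizes give Monte-Carlo standard
errors of a few percentage points on the disparity means while keeping a
full five-method comparison to a few minutes on one core; they are the
package's default study conditions, stated here so that any rerun is
interpreted against them. Everything — population draws, fits, search,
evaluation — derives from the single master seed.

Qualitative picture on the defaults (as asserted by the acceptance
tests): SOTA shows a large positive disparity; NO_SES reduces but does
not remove it (history features still proxy for group); RACE_UNAWARE
reduces it further, to within noise of zero; NO_ML is statistically
indistinguishable from zero; and NO_ML pays by far the largest
efficiency gap while RACE_AWARE pays the smallest among the
interventions. The original study's headline percentages were computed
on a real clinic dataset that is not available; only this ordering, not
those numbers, is reproduced here.

One deviation from the idealized picture is real and worth
understanding: RACE_AWARE does not land *at* zero disparity on these
small days — it overshoots mildly in favour of group B (around −13% to
−21% across seeds, several standard errors from zero, unchanged under a
5× larger search budget). The cause is discreteness. A 12-patient day
carries its expected wait in roughly two 30-minute lumps; placing a lump
on the 70% group raises that group's mean by ~2.3× less than placing it
on the 30% group, so the min-max-group optimum systematically prefers
loading the majority, and exact equalization is unattainable. Using
unconditional waits in the objective would overshoot on the *positive*
side by roughly the show-rate ratio (~+19%), so no composition of this
objective hits zero at this day size; at clinic scale, where group means
are near-continuous, the min-max optimum equalizes tightly. The
acceptance suite asserts the zero-within-3-SE property anyway and that
assertion fails by design honesty rather than being weakened.

# Degenerate inputs and numerical conventions

Probabilities exactly 0 or 1 are legal everywhere (weights of impossible
show vectors vanish; conditional waits of never-showing patients are
defined as 0). Degenerate training histories (all shows or all no-shows)
raise a fit error rather than returning a separating model. Optimality
gaps require a positive reference cost; disparity requires both groups
nonempty. Objective comparisons inside the search use a $10^{-9}$
tolerance; quota satisfaction uses $10^{-12}$. Assignment encodings are
compared lexicographically for tie-breaking, making every reported
optimum deterministic.

# Known limitations

* Single provider, homogeneous slot lengths, no walk-ins or
  cancellations, no within-day rescheduling.
* The min-max race-unaware objective can be substantially more expensive
  than the traditional one on small instances — with only two overbooked
  slots the individual min-max has little room to trade — so its
  efficiency loss here is larger than a production formulation (e.g.
  lexicographic min-max) would show.
* All fairness conclusions are relative to the synthetic population's
  proxy structure; none of the generator's magnitudes are calibrated to
  a real clinic.
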