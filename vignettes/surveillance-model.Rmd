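---
title: "Modelling post-operative aortic surveillance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-operative aortic surveillance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortasurv)
```

## The question and the model

After elective open or endovascular aortic surgery, patients are scheduled
for surveillance visits with CTA imaging — typically first at 6 months, then
at widening intervals. Whether that first visit earns its cost and radiation
exposure depends on how much pathology it can catch. `aortasurv` frames the
question as a discrete-time multi-state problem: between consecutive
scheduled visits, a patient either stays healthy (`H`), develops a
complication (`C`: a new endoleak, a new or anastomotic aneurysm, or growth
of a residual aneurysm by at least 1 cm against the immediate post-operative
baseline), undergoes reintervention (`R`), or dies (`D`, any cause).

Severity is ordered `H < C < R < D` and movement is one-way: `H` may move to
any state, `C` to `R` or `D`, `R` only to `D`, and `D` is absorbing. The
states are mutually exclusive by severity, so "complication" means
*ever-complicated, not yet reintervened, alive*, and "reintervention" means
*ever-reintervened, alive*. There is no recovery transition — a detected
endoleak may resolve clinically, but the patient's surveillance history never
returns to "nothing has happened", which is the quantity a skipped visit
puts at risk.

Because event rates after aortic surgery are visibly non-constant over time
(early endoleaks dominate the first year; censoring and attrition dominate
later), one transition matrix per 6-month interval is estimated rather than
a single homogeneous matrix. A 6-month step matches the scheduled visit
grid, and a coarser step than the visit grid would discard exactly the
information the question is about, while a finer one would pretend to
resolution the visit-based detection cannot support.

## Estimation

For interval $k$ spanning $((k-1)\,L,\;k\,L]$ months ($L = 6$ by default)
and origin state $s$, the transition probability to state $t$ is estimated
as

$$\hat p_k(s \to t) \;=\; \frac{n_k(s \to t)}{n_k(s) - c_k(s)},$$

where $n_k(s)$ counts patients in state $s$ at the interval's start,
$n_k(s \to t)$ those observed in $t$ at its end, and $c_k(s)$ those whose
follow-up ended inside the interval without an event (complete cases within
the interval). The diagonal receives the remainder, so every estimated row
sums to one exactly and forbidden cells are structurally zero. An origin
state with an empty post-censoring risk set yields an identity row — no
information is read as no movement — with a warning when information was
actually lost (the state had been occupied before, or everyone in it was
censored); a state no patient has reached yet is silently empty.

Conventions, chosen once and asserted in the test suite:

* **Interval boundaries.** Intervals are half-open on the left, so an event
  at exactly 6.0 months belongs to the first interval. "At 6 months"
  summaries therefore include what the 6-month visit itself finds, which is
  the reading a visit-based detection process implies.
* **Worst state wins.** A patient with several qualifying events in one
  interval lands in the worst state (`D > R > C`); a complication and its
  reintervention in the same interval place the patient directly in `R`.
* **Censoring.** A patient whose follow-up ends within an interval without
  an event is removed from that interval's denominator entirely, including
  a follow-up that ends exactly at the interval's start. This is
  conservative (no half-interval exposure credit) and mirrors the
  synthetic generator exactly, making parameter recovery unbiased.
* **Times.** Months from discharge, continuous; visit-detected events carry
  the visit time. Interval-censored onset is *not* back-imputed — the model
  asks what a visit would have found, not when the pathology began.

Occupancy (the probability of each state at each visit) is obtained exactly
by propagating the initial distribution through the matrix product, and by
seeded simulation of patient trajectories when relative frequencies with
sampling noise are wanted (the two agree within binomial error; the test
suite holds simulation at $n = 10{,}000$ to within $3\sqrt{p(1-p)/n}$ per
cell). Mass conservation and monotone absorption (non-decreasing `D`,
non-increasing `H`) hold by construction and are asserted per run.

## Kaplan–Meier estimation

The product-limit estimator is implemented from scratch because its risk
tables are part of the deliverable, with the standard conventions stated
explicitly: tied events and censorings at one time keep the censored
subjects in the risk set (events first); confidence bands use Greenwood's
variance on the $\log(-\log S)$ scale, which respects $[0, 1]$. Agreement
with `survival::survfit` is enforced to $10^{-10}$ on randomly generated
censored data in the tests; `survival` is used only as an oracle, never as
the implementation.

## Number needed to harm

For a skipped visit at step $k$ and harm-state set $A \subseteq \{C, R,
D\}$,

$$\mathrm{NNH} = \Bigl(\sum_{s \in A} \pi_k(s)\Bigr)^{-1},$$

the reciprocal of the harm-state occupancy at that visit. This is a
deliberate worst-case reading: it assumes every patient occupying a harm
state at the skipped visit goes unnoticed and unsalvaged. The assumption is
attached verbatim to every NNH object and CSV report. Both the two-decimal
reciprocal and its ceiling (the smallest whole number of patients who must
all skip the visit for one harm to be missed) are reported. A zero harm
occupancy raises an explicit "NNH undefined" error; the pipeline records
such strata as `NA` rows rather than inventing an infinite NNH.

Worked at the published 6-month occupancy (95.25% healthy, 2.58%
complication, 1.67% reintervention, 0.50% death): harm $\{R\}$ gives
$1/0.0167 = 59.88$ (ceiling 60); harm $\{C, R\}$ gives $1/0.0425 = 23.53$
(ceiling 24) — two-decimal inputs, so the last digit can differ by one or
two hundredths from a value computed on unrounded frequencies.

```{r nnh-worked}
step1 <- diag(4)
step1[1, ] <- c(0.9525, 0.0258, 0.0167, 0.0050)
occ <- propagate_occupancy(mcm(list(step1)))
nnh(occ, harm_states = "R", at_step = 1)
nnh(occ, harm_states = c("C", "R"), at_step = 1)
```

## The synthetic cohort generator

Real surveillance records of this kind are not distributable, so the
package ships a generator whose statistical structure matches what the
estimator assumes, making every downstream stage testable and every
estimator property checkable against a known truth.

Each patient-interval is a single categorical draw over censoring, the
allowed transitions and staying put, with cell probabilities
$\bigl(c_k,\; (1-c_k)\,h_{k}(s\to t),\; (1-c_k)(1 - \sum_t h_k)\bigr)$.
Putting the censoring competition *inside* the draw this way makes the
complete-case estimator exactly unbiased for the generating hazards
$h_k(s \to t)$, so recovery tests are sharp: at $n = 50{,}000$ every
estimated cell sits within three binomial standard errors of its generating
value and the propagated occupancy within half a percentage point per cell
(both asserted in the acceptance tests; these sizes keep the whole suite
under a quarter of a minute on one core).

Defaults describe a plausible elective aortic cohort: 464 patients, 25%
endovascular; abdominal pathology in 80% of endovascular and 32% of open
patients (≈45% overall); ages centred near 75 (endovascular) and 64 (open)
years; a 36-month horizon in 6-month steps. The per-approach hazard tables
give the endovascular-like stratum a much larger early complication hazard
(endoleaks dominate its early follow-up; none occur after open repair,
whose complications are anastomotic aneurysms and residual-sac growth), and
per-interval censoring is light (2%) for the first 18 months, then rises
steeply (15%, 25%, 35%) — surveillance attrition grows markedly after a
year and a half. These shapes are *illustrative*: the per-interval matrices
behind the published occupancies are not publicly available, and no claim
of reconstructing them is made. Seeding is per patient — each record is
driven by a substream derived from `(seed, patient index)` — so a cohort of
25 is bit-for-bit the first 25 patients of a cohort of 80 under the same
seed.

What the generator deliberately does **not** emulate: correlations between
baseline covariates and hazards beyond the approach stratum (age, pathology
and level are decorative covariates), measurement error in diameters,
irregular visit schedules, or informative censoring. Passing recovery tests
therefore show the estimator is correct *under the model's own assumptions*;
they cannot show that real surveillance data satisfy those assumptions.

The generator emulates the *post-eligibility* cohort (all exclusion flags
false, ages ≥ 18, at least two CTA visits recorded), since the eligibility
cascade precedes cohort assembly in the study design; re-excluding early
censors through the visit-count criterion would otherwise bias recovery
experiments. The cascade itself — age < 18, history of dissection, planned
further aortic surgery, emergent surgery, in-hospital aortic event, fewer
than two CTA follow-up visits, in that fixed order, each patient tallied
under the first criterion that removes them — is exercised on constructed
micro-cohorts. The order within the cascade is a package choice (a flow
chart fixes the set, not the attribution); fixing it makes tallies
deterministic.

## Other resolved design points

* **Endoleak subtypes** (Ia–IV) all qualify as aortic events; the subtype is
  retained for reporting only.
* **Death of any cause** counts, and composite ties break by severity
  (death > reintervention > aortic event).
* **Intra-operative endoleaks** resolved before discharge do not count as
  events at time 0: the data model starts at discharge, consistent with
  excluding in-hospital aortic events.
* **Diameter progression** is measured against the immediate post-operative
  baseline, not the previous visit, with a ≥ 10 mm threshold applied at
  derivation time (sub-threshold entries are ignored, not errors).
* **Secondary-outcome curves** (endoleak, new aneurysm, diameter
  progression) censor at end of follow-up, including at death — no
  competing-risks adjustment, matching standard per-outcome product-limit
  reporting.
* **Report determinism.** Bundles carry no wall-clock timestamps and are
  staged to a temporary directory before being copied, so re-running a
  seeded pipeline reproduces every file byte for byte and failures never
  leave partial bundles.

## Numerical tolerances

Row-stochasticity is enforced at $10^{-12}$, occupancy mass conservation at
$10^{-9}$ (exact propagation accumulates only a handful of products of
numbers in $[0,1]$), and the estimator-vs-oracle check for the product-limit
curve at $10^{-10}$. Reported percentages carry two decimals. NNH ceilings
are taken on the unrounded reciprocal.

## Limitations

The model inherits the worst-case NNH reading (every harm at a skipped
visit is missed), the no-recovery structure, and visit-time event dating.
Per-interval estimates become unstable where censoring thins the late risk
sets — exactly the regime the rising default censoring emulates — and the
identity-row fallback then freezes occupancy rather than extrapolating. No
covariate-adjusted transition models are attempted: with event counts this
size, regression on transition probabilities would be over-fitting dressed
up as adjustment.
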