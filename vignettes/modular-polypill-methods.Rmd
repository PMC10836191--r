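---
title: "Modelling modular titratable polypills: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling modular titratable polypills: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modpolypill)
```

## The problem

A modular titratable polypill assembles single-drug tablet units —
interlocking dome/dimple disks in a capsule (design 1) or annular disks
stacked on a dissolvable rod (design 2) — so each drug's dose can be
adjusted independently. This package covers the three quantitative workflows
such a product raises: a cost-effectiveness comparison of a variable-dose
(VD) polypill against a fixed-dose combination (FDC) polypill and standard
care in cardiovascular prevention; the compendial quality-control
computations applied to the modular tablets; and the integer dose-titration
problem of picking units that realize a prescribed dose within the
capsule/rod capacity.

## The Markov cohort model

A cohort of 60-year-olds with cardiovascular risk but no prior myocardial
infarction (MI) moves annually between five states:

* **OnTx-NoSE** — on treatment, no side effects so far;
* **OnTx-PostSE** — continued treatment after experiencing side effects
  (arm-specific extra MI risk, annual side-effect cost, utility decrement);
* **OffTx** — discontinued, whether through side effects or non/low
  adherence; a single off-treatment MI probability applies regardless of the
  reason (the two reasons can be tracked separately via
  `split_offtx = TRUE`, and the traces lump exactly);
* **Post-MI** — survived an MI; fully adherent thereafter, elevated
  mortality, annual care plus monthly medication costs;
* **Dead** — absorbing; also reached directly by the fatal fraction
  `p_mi_fatal` of MI events and by age-indexed background mortality.

Structural assumptions encoded (and tested): discontinuation happens only
through side effects or non-adherence; post-MI patients never discontinue;
side-effect status changes MI risk only through the arm's per-state MI
parameters.

**Competing risks.** Several annual probabilities apply in each state. They
are combined on the rate scale: `r_i = -log(1 - p_i)`, the state is left with
probability `1 - exp(-sum(r_i))`, and that mass is allocated proportionally
to the rates. A single risk therefore passes through unchanged, and two 0.5
risks give 0.375 each (closed forms in the tests).

**Recurrent side effects.** Patients in OnTx-PostSE remain exposed to the
side-effect hazard and to the discontinuation it may trigger. Besides being
clinically sensible, this is what makes the model internally consistent: if
side-effect events could only happen once, the side-effect hazard would
compete with MI, non-adherence and death in OnTx-NoSE but not in
OnTx-PostSE, and setting the side-effect cost, disutility and MI-risk change
to zero would still leave the two on-treatment states behaving differently.
With recurrence, clinically neutral side effects make the two states exactly
lumpable — the 5-state model reproduces a 4-state reduction to 1e-9, which
the test suite asserts.

**MI as a transition event.** MI is a transition with a one-time cost on
entry into Post-MI, not a tunnel state: the cycle length is one year, so
acute-phase costs fit a transition reward. The fatal fraction of MI goes
straight to Dead, merged with background death in a single probability;
consequently the one-time cost matrix, which is indexed by (from, to),
cannot attribute any share of the →Dead flow to MI, and immediately fatal
events accrue no event cost. If fatal-MI costs matter for an analysis, they
can be folded into `mi_event_cost` scaled by `1/(1 - p_mi_fatal)`.

**Rewards and discounting.** Rewards are credited to the state occupied at
the start of each cycle; the trapezoid-style half-cycle correction is
available via `half_cycle = TRUE` but off by default (the simplest reading
of an annual-cycle cohort model). Costs and QALYs are both discounted at 3%
per year by default. The source analysis names only costs when stating the
3% rate but applies discounting to "all results" in its summary figure; we
default to discounting both, with `discount_rate_qaly` exposed separately
for the other reading.

**Horizon and mortality.** "Lifetime" is implemented as annual cycles to age
100 (40 cycles from the base-case start age of 60); survivors at the horizon
accrue nothing further. Background mortality is an age-indexed table or
function; the bundled stand-in is Gompertz-like,
`q(a) = min(1, 5e-5 * exp(0.085 a))`, giving roughly 0.8% annual mortality
at 60 and 10% at 90 — a plausible all-cause schedule when no life table is
supplied.

## CEA analytics

Strategies are ranked by effect; strictly dominated ones (another strategy
no costlier and no less effective, one strictly) are flagged, then extended
dominance is removed iteratively: a strategy whose incremental ICER exceeds
that of the next more effective survivor leaves the frontier. Extended
dominance is standard CEA practice for three or more strategies; with the
base-case arm ordering it never changes the answer, but the machinery is
required for arbitrary inputs. Frontier ICERs are strictly increasing by
construction, which the tests assert on random instances, and the ranking is
checked cell-by-cell against an independent willingness-to-pay-sweep oracle
on an exhaustive lattice of three-strategy outcomes.

Conventions worth stating:

* exact cost-and-effect ties are both kept and flagged `equivalent` (no
  information favours either);
* boundary ICER ties (collinear points) stay on the frontier — extended
  dominance uses a strict inequality;
* `cost_effective_choice()` returns the most effective frontier strategy
  whose ICER does not exceed the willingness-to-pay (default
  $100,000/QALY), falling back to the least costly strategy.

One-way sensitivity analysis re-solves every arm on a parameter grid
(default 41 points) and refines each flip of the predicate "the target
strategy is the cost-effective choice" by bisection to 1e-6 of the parameter
range. On toy models with affine parameter-to-cost maps the recovered
threshold matches the analytic crossing to the same tolerance.

## Quality-control conventions

* Acceptance value `AV = |M - X̄| + k s`, `k = 2.4` for n = 10, `M` the mean
  clipped to [98.5, 101.5]%; **pass strictly below 15.0** (the source states
  "less than").
* Weight variation: max per-unit deviation from the mean **≤ 7.5%
  (inclusive)** for 130–324 mg tablets; other mean weights require an
  explicit limit. A `usp_classic` mode (≤ 2 units beyond the limit, none
  beyond twice) is selectable.
* Friability: loss **≤ 1.0% (inclusive)** and no breakage — breakage fails
  regardless of loss.
* Disintegration: all six units within 900 s (inclusive).
* Dissolution: single-stage batch mean at the criterion time — exact sample
  point when present, otherwise linear interpolation between bracketing
  points — **≥ Q (inclusive)**. Multi-stage S1/S2/S3 staging is out of
  scope.
* All limit comparisons carry a 1e-9 guard so a measurement exactly at a
  limit is classified by the stated convention rather than by floating-point
  representation noise.
* Sample standard deviations use the n − 1 denominator throughout.

The bundled criteria table (`dissolution_criteria()`) transcribes the
per-drug monograph limits. Two source irregularities are preserved
explicitly rather than silently resolved: the 75%/45-min row printed a
second time under the name isoniazid is recorded as ethambutol with a note
flag, and the prednisone row uses the parenthetical monograph limit
(80%/30 min) although the surrounding text mentions a 60-min sampling time.
Hardness has no compendial limit, so `hardness_summary()` reports mean and
sd only. Tablet thickness has no acceptance criterion and is not computed.

## Dose titration

Doses are scaled to exact integers (a common power of ten; 2.5 and 12.5 mg
steps need one digit), so feasibility is never decided by float equality.
The solver is a dynamic program over achievable integer doses minimizing
total unit count, with ties broken by fewer distinct strengths, then by
preferring larger strengths first. The objective and tie-breaks are this
package's choice — attainability within capacity is the requirement; fewest
units is the natural packing objective. Infeasible targets raise a
`dose_infeasible` condition carrying the nearest achievable doses below and
above. Capacities: design 1 ≤ 5 units (AA capsule) or ≤ 8 (000 capsule),
design 2 ≤ 10 (rod); mixed designs in one polypill are rejected. The tests
verify minimality against exhaustive enumeration for every 2.5 mg multiple
up to 200 mg over the bundled strength sets.

## The synthetic world

No literature-calibrated inputs ship with the package; the generator stands
in for them so every workflow is testable offline.

* `gen_cea_params()` draws each probability, utility and cost uniformly
  within documented ranges (`default_cea_ranges()`), then enforces the arm
  ordering expected of the three strategies: standard care has the lowest
  drug cost and highest non-adherence; the personalized VD polypill's
  side-effect probability never exceeds the FDC's. The ranges are chosen
  once to straddle the decision-relevant magnitudes (the VD monthly cost
  range spans $129, the FDC side-effect range spans 0.68, the on-treatment
  MI ranges span 1.1%/1.4% per year) so threshold searches genuinely cross;
  they are stand-ins, not estimates.
* `gen_tablet_batch()` draws weights, contents, disintegration times,
  friability and hardness around nominal values that comfortably satisfy
  every limit, and builds 4-vessel dissolution profiles from a Weibull curve
  `F(t) = F_max (1 - exp(-(t/scale)^shape))` with additive observation
  noise. With all CVs and noise at zero the batch reproduces its nominal
  values exactly.
* Each output block consumes its own deterministic sub-seed, so adding a
  field to one block never perturbs another block's draws.

What a green test does **not** establish: the synthetic draws say nothing
about the actual magnitude of any ICER for a real product — they exercise
the machinery (dominance handling, threshold location, validation) under
wide but arbitrary ranges. Real analyses should supply transcribed
parameter tables through `read_cea_params()`, whose JSON schema mirrors the
constructors field-for-field.

## Validation against the micro-simulation oracle

`simulate_individuals()` is an independent implementation: per-cycle
categorical sampling of individual trajectories with per-individual
discounted reward accumulation. The cohort trace is compared with the
empirical occupancy of 10^6 individuals on 20 random 5-state models. One
statistical subtlety is handled deliberately: "every state at every cycle
within 3 standard errors" across 1,100 simultaneous binomial comparisons is
expected to fail ~3 times under a *correct* engine (1,100 × 0.0027), so the
acceptance test applies the 3-SE rule at its own error rate — every cell
must lie inside the Bonferroni-adjusted 3-SE quantile (z ≈ 4.8) and the
number of 3-SE exceedances must stay inside the 99.9% binomial envelope.
Both bounds follow from the 3-SE tail probability alone and were fixed
before running; a genuine engine defect produces standardized deviations
orders of magnitude beyond either bound.

## Numerical conventions

* Transition rows must sum to 1 within 1e-9; deviations below 1e-12
  (floating-point dust) are renormalized silently, anything larger is an
  error naming the offending state and cycle.
* Absorbing rows must be exact unit vectors onto themselves.
* Monthly costs are annualized (×12) before entering cycle rewards.
* Utilities are clamped to [0, 1] at validation, never silently rescaled;
  the side-effect disutility is subtracted from the on-treatment utility
  with a floor at 0.
* Bisection tolerance for sensitivity thresholds: 1e-6 of the swept range.

## Known limitations

* MI is the only cardiovascular endpoint; stroke and other events are out of
  scope, as are subgroups and patient heterogeneity.
* One-way sensitivity only; probabilistic sensitivity analysis (CEAC,
  value-of-information) is a non-goal.
* The yearly competing-risk composition assumes at most one state-changing
  event per cycle beyond the fatal/non-fatal MI split.
* Dissolution testing is single-stage on the tested vessels; no
  release-kinetics model fitting.
* The titration solver packs by unit count only; geometric/volumetric
  packing from tablet thickness and drug–drug compatibility are out of
  scope.
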