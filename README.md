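# modpolypill

Health-economic and pharmaceutical quality tooling for **modular titratable
polypills** — single capsules or rod-assembled stacks built from single-drug
tablet units, so that each drug's dose can be titrated independently (unlike a
fixed-dose combination, FDC). The package is aimed at health-economics and
formulation scientists who want to (i) compare a variable-dose (VD) modular
polypill against an FDC polypill and standard care in a Markov cohort
cost-effectiveness analysis, (ii) run the compendial (USP-style) quality
checks on modular tablet batches, and (iii) solve the integer dose-titration
problem of assembling a prescribed dose from a catalogue of unit strengths
under capsule/rod capacity limits.

## What it computes

**Markov cohort engine.** A cohort distributed over health states
`s ∈ {OnTx-NoSE, OnTx-PostSE, OffTx, Post-MI, Dead}` evolves by
`π_{t+1} = π_t P_t` with cycle length 1 year and age-indexed transition
matrices `P_t`. Discounted totals over a horizon of `T` cycles are

    Cost = Σ_{t=0}^{T-1} (1+r)^{-t} ( π_t c + Σ_{i,j} π_t[i] P_t[i,j] C_once[i,j] )
    QALY = Σ_{t=0}^{T-1} (1+r)^{-t} ( π_t u )

with per-state annual costs `c`, utilities `u ∈ [0,1]`, one-time transition
costs `C_once` (e.g. an acute MI event), and `r = 0.03` by default (half-cycle
correction optional). Competing annual risks are combined on the rate scale:
`r_i = −ln(1−p_i)`, exit probability `1 − exp(−Σ r_i)` allocated
proportionally to rates.

**CEA analytics.** Pairwise ICER `ΔC/ΔE` (USD/QALY), strict dominance,
iterative extended dominance, the efficiency frontier with strictly
increasing ICERs, the cost-effective choice at a willingness-to-pay
threshold (default $100,000/QALY), and one-way sensitivity sweeps with
bisection-refined decision thresholds.

**USP-style QC.** Content-uniformity acceptance value
`AV = |M − X̄| + k·s` (k = 2.4 for n = 10, reference value `M` = `X̄` clipped
to [98.5, 101.5]%, pass iff AV < 15.0); weight variation (≤ 7.5% for 130–324
mg tablets); friability (≤ 1% loss, no breakage); disintegration (≤ 15 min);
dissolution against per-drug `NLT Q% at t min` monograph limits (bundled
criteria table); hardness summary.

**Dose titration.** Exact integer change-making: unit counts with
`Σ count·strength = target` exactly (rational mg arithmetic), minimizing the
number of units, with capacity checks — design 1 interlocking tablets fit an
AA capsule (≤ 5 units) or a 000 capsule (≤ 8); design 2 annular disks stack
on a rod (≤ 10).

**Synthetic data.** Seeded generators for CEA parameter sets (uniform draws
within documented ranges, arm-ordering constraints enforced) and tablet-batch
measurements, plus a micro-simulation oracle (`simulate_individuals()`) used
to validate the cohort engine.

## Worked example

```r
library(modpolypill)

params <- gen_cea_params(generator_spec(seed = 4))
bc <- run_three_arm_base_case(params$arms, params$shared)
print(bc$result)
#> Cost-effectiveness ranking (sorted by increasing effect):
#>           name    cost  effect      status    icer
#>            FDC 21151.2 12.7055   dominated      NA
#>  standard_care 17741.1 13.0859 on-frontier      NA
#>             VD 24904.5 13.2146 on-frontier 55635.2
bc$choice
#> [1] "VD"
```

Read: under this synthetic parameter draw the FDC arm is strictly dominated
(costlier and less effective than standard care); VD buys 0.129 extra QALYs
over standard care at $55,635 per QALY, below the $100,000/QALY threshold, so
VD is the cost-effective choice. Sweeping the VD monthly cost upward flips
the decision at the bisection-located threshold:

```r
fn <- function(v) { a <- params$arms; a$VD$monthly_drug_cost <- v
                    run_three_arm_base_case(a, params$shared)$result }
sw <- one_way_sensitivity(fn, "vd_monthly_cost",
                          low = params$arms$VD$monthly_drug_cost, high = 3000,
                          wtp = params$shared$wtp, target = "VD", n_grid = 21)
sw$threshold
#> [1] 242.1733
```

Titration and QC:

```r
solve_drug_dose(17.5, c(10, 2.5))
#> 17.5 mg = 1 x 10 mg + 3 x 2.5 mg (4 units)
assemble_polypill(c(rosuvastatin = 5, lisinopril = 5,
                    hydrochlorothiazide = 12.5, acetylsalicylic_acid = 81),
                  design = 1)$container
#> [1] "AA"

batch <- gen_tablet_batch(generator_spec(seed = 1), drug = "rosuvastatin")
r <- qc_report(batch)
c(AV = r$content_uniformity$av, all_pass = r$all_pass)
#>       AV all_pass
#> 3.988276 1.000000
```

A command-line front end lives at `inst/scripts/modpolypill-cli.R`
(subcommands `cea`, `titrate`, `qc`, `synth`).

## Documentation

The methods vignette (`vignettes/modular-polypill-methods.Rmd`) describes the
model structure, its assumptions, the synthetic-data design, numerical
conventions and known limitations.
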