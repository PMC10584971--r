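---
title: "Methods: a microsimulation model of multi-cycle IVF cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a microsimulation model of multi-cycle IVF cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivfcea)
```

## The decision problem

Couples with PCOS-related infertility entering an assisted-reproduction
program typically undergo a sequence of IVF cycles until an ongoing
pregnancy is achieved or treatment is abandoned. A public payer covering
gonadotropins and procedure costs cares about three quantities per
stimulation strategy: the mean cost of the whole program per patient, the
probability of an ongoing pregnancy (confirmed at 12 gestational weeks),
and their ratio — the cost per pregnancy. `ivfcea` estimates all three by
patient-level Monte Carlo simulation and compares two
controlled-ovarian-hyperstimulation strategies: rFSH with daily oral
myo-inositol supplementation versus rFSH alone. Myo-inositol, an FSH
second messenger in granulosa cells, is reported to improve oocyte quality
and lower the gonadotropin dose needed in PCOS patients; in the model this
enters purely through its consequences — slightly better fresh-cycle
transition probabilities and a cheaper stimulation item — not through any
pharmacological mechanism.

## Model structure

A patient's program is a finite decision tree of at most three cycles.

**Fresh cycle.** Stimulation; oocyte pickup; usable-oocyte check;
fertilization technique (ICSI with probability `icsi_share`, otherwise
conventional IVF); technique-specific fertilization, embryo-transfer and
ongoing-pregnancy events. The first failed event terminates the cycle with
a terminal stage (`pickup_failed`, `no_usable_oocytes`,
`fertilization_failed`, `transfer_not_reached`, `transfer_failed`) or the
cycle ends `pregnant`. Costs accrue conditionally on the stage being
reached: stimulation drug (arm-specific), other hormones, monitoring
ultrasounds and consultations always; pickup and its ultrasound on a
successful pickup; the IVF laboratory fee or the ICSI procedure plus ICSI
laboratory fee at technique assignment; the technique's catheter and
disposables on a completed transfer.

**Frozen cycle.** Thawing (always paying the freeze-and-thaw item), embryo
survival, then the transfer catheter and the ongoing-pregnancy event.
Frozen cycles carry no stimulation, monitoring or consultation costs: only
the two items listed for them in the cost table. This minimal frozen cost
set reproduces the per-arm program cost totals, which a recurring
monitoring package would overshoot.

**Sequencing.** Cycle 1 is always fresh. After a failed cycle 1 (any
non-pregnant terminal stage, including a failed pickup) the patient starts
cycle 2 with probability `start_cycle2_after_failure`, fresh with
probability `fresh_share_cycle2` and frozen otherwise. A patient who is
still not pregnant after the cycle-2 stage — whether the second cycle was
run or declined — starts cycle 3 with probability
`start_cycle3_after_failure` and fresh share `fresh_share_cycle3`. The
program stops at the first pregnancy. We deliberately let a patient who
declined cycle 2 still take up cycle 3: treating the first refusal as
absorbing suppresses part of the tabulated third-cycle uptake and pulls
the program pregnancy probability below the published overall rates,
while the non-absorbing reading reproduces them (this is what the
acceptance checks exercise). `expected_program_outcomes()` implements
exactly this structure.

Two pathway details are configurable rather than fixed:

* **Frozen-embryo availability.** The tabulated fresh/frozen shares impose
  no biological gating, so the default mode `table_faithful` offers frozen
  cycles unconditionally at those shares. Mode `strict_embryo_gating`
  additionally requires that some earlier fresh cycle reached a successful
  fertilization (so a surplus embryo could have been cryopreserved) and
  falls back to a fresh cycle otherwise. The published totals are
  reproduced without gating, which is why it is the documented variant,
  not the default.
* **OHSS treatment cost.** The cost table prices OHSS treatment at
  €90–150 but no frequency of application is stated, and the per-arm cost
  totals are reproduced without it. The default cost model therefore
  excludes it; `ohss_prob` accrues it per fresh cycle with the given
  probability for users who want it.

One embryo is transferred per transfer event; there is no twin-pregnancy
or surplus-embryo inventory accounting (the tables carry no multiplicity
information), no OHSS cancellation pathway, no live-birth extrapolation
and no discounting. The frozen-cycle "clinical pregnancy after survived
embryo" row is treated as the same 12-week ongoing-pregnancy endpoint as
the fresh-cycle rows.

## Parameters and sampling

Every parameter is a closed interval `[lo, hi]` — a probability range as a
fraction of `[0, 1]` or a unit cost range in euros — and is drawn uniformly
at *every use*: each stage event of each cycle of each patient redraws its
probability, and each accrued item redraws its price. `ivf_parameters()`
ships the reference tables (Italian unit costs; probabilities pooled from
published PCOS ART outcomes and clinical experience). Notable readings of
those tables:

* The "IVF versus ICSI" row (10–50%) is the probability of *ICSI*. Under
  this reading the model reproduces the published overall pregnancy rates
  (≈0.38 vs ≈0.36); reading it as the probability of IVF pushes both arms
  above 0.40 because the ICSI branch has the stronger transition product.
* The single printed pickup-ultrasound price (€30) is the degenerate range
  `[30, 30]`; degenerate ranges are valid everywhere.
* The myo-inositol supplement's own cost is contained in the cheaper
  supplemented-stimulation range €900–1900 (versus €1000–2000 for rFSH
  alone); there is no separate supplement item.
* The IVF (€300–600) and ICSI (€300–700) laboratory fees are distinct
  items, and the ICSI branch additionally pays the ICSI procedure
  (€500–700).

Redrawing at every use (rather than freezing one draw per patient) makes
every program expectation exactly multilinear in the parameters, which is
what lets the midpoint evaluation below be exact. Freezing one draw per
patient instead would correlate a patient's cycles, shifting program-level
expectations by terms of order `var(U(lo, hi)) = (hi - lo)^2 / 12` —
second-order in the range widths, hence small for tables as narrow as
these.

## The analytic oracle

Since `E[U(lo, hi)] = (lo + hi)/2` and the tree value is multilinear in
independently drawn parameters, evaluating the tree at range midpoints
gives the exact simulation mean. The package carries this computation
twice: a closed-form evaluation (`expected_program_outcomes()`, production)
and a flat exhaustive enumeration of every terminal path of the
three-cycle tree (test-only, in the test helpers). The two agree to
machine precision across the reference tables and randomized scenarios,
which guards against structural transcription errors in the pathway; the
simulation in turn is required to match them within three Monte Carlo
standard errors. Useful exact identities, all tested: pregnancy is
non-decreasing in each of the 13 stage/continuation probabilities; costs
never affect transitions; setting both continuation probabilities to zero
collapses the program to a single fresh cycle; an all-certain IVF path
costs exactly the hand-summed item total (€3505 at midpoint prices in the
supplemented arm).

## Cohorts, dispersions and comparison

`run_cohort()` simulates `n` patients (default 100,000 — the scale of a
national annual ART caseload) on a single seeded stream, vectorized over
patients; `ivf_psa()` runs both arms (seeds `seed` and `seed + 1`) and
compares them. The per-patient scalar walker `simulate_patient()`
implements the same tree for audit and trajectory export; both routes are
held to the same oracle in the tests.

Dispersion conventions:

* **Cost**: SD across patients. Pathway variability (how far each patient
  gets, how many cycles) dominates this spread, which is why its
  coefficient of variation is large (≈40%).
* **Pregnancy rate**: per-patient outcomes are binary, so a patient-level
  SD (~0.49) is uninformative; we report the SD of pregnancy fractions
  over consecutive disjoint sub-cohorts of `subcohort_size` patients,
  default 150. The default is a declared convention, chosen because
  binomial dispersion at that block size has the magnitude conventionally
  reported for cohort rates (~0.04); no aggregation unit is canonical.
  A trailing partial sub-cohort is dropped; with fewer than two complete
  sub-cohorts the SD is reported as `NA`.
* **Cost per pregnancy**: point estimate `mean_cost / pregnancy_rate` on
  the unrounded rate; dispersion `sd_cost / pregnancy_rate`. With zero
  pregnancies it is undefined (`NA`), never infinite.

Between-arm inference uses large-sample z tests (unequal-variance
two-sample on per-patient costs; pooled two-proportion on pregnancy) —
at n = 100,000 the normal approximation is exact for practical purposes
and t corrections are pointless. Human-readable reports floor the
displayed p-value at "< 0.0001"; JSON keeps full precision. The dominance
verdict is strict: a strategy dominates only if it is simultaneously
cheaper and more effective; ties and trade-offs are both reported as
`tradeoff`, and undefined test statistics (e.g. single-patient cohorts)
are `NA` rather than fabricated.

## Scenario generation and what it does (not) show

`random_scenario()` draws structurally valid parameter tables: probability
ranges placed uniformly in `[0, 1]` with widths inside `width_bounds`
(default 0.05–0.4, bracketing the widths of the reference tables), and
cost ranges around log-uniform midpoints between €10 and €5000 (the order
of magnitude of real ART unit costs, without degenerate zeros).
`degenerate_scenario()` pins probabilities at 0/1 for exact-outcome edge
cases. These scenarios exercise every branch of the engine and the oracle
identities without any external data; they emulate the *statistical shape*
of real parameter tables (independent uniform ranges), not clinical
correlations between stages, secular trends, or patient heterogeneity —
passing them validates the arithmetic of the model, not the realism of
any particular parameterization.

`sensitivity_scan()` performs one-way deterministic sensitivity analysis:
one parameter swept over a grid, all others at base midpoints, outcomes
from the analytic oracle.

## Numerical and reproducibility notes

* All randomness flows from user-supplied integer seeds through R's
  default generator; the same configuration is bit-reproducible, and
  result files contain no timestamps so reruns are byte-identical.
* Patients are independent; cohort summaries of the headline outcomes are
  invariant to patient order (the sub-cohort rate SD, by construction, is
  a block statistic and depends on the fixed simulation order).
* Parameter validation is collected, not fail-fast: loaders report every
  violation (inverted ranges, probabilities outside `[0, 1]`, negative
  costs, missing rows) at once. Simulation entry points reject invalid
  tables before drawing anything.
* The parameter CSV stores probabilities in percent exactly as printed in
  the source tables, so files remain visually checkable; conversion to
  fractions happens at load and round-trips exactly.
* Test problem sizes: the acceptance-style checks run 100,000 patients per
  arm (seconds of CPU); oracle-equivalence checks use 20,000–40,000
  patients per scenario, which keeps three-standard-error bands tight to
  ~1% while the whole suite stays fast.

## Known limitations

The model inherits the limitations of its parameter tables: transition
probabilities pooled from heterogeneous published cohorts and clinical
experience, Italian unit costs not transferable to other systems without
re-pricing, and a virtual PCOS population (under 40, BMI < 30, no
comorbidities) that does not represent all IVF patients. Uniform
independent ranges ignore correlations (a clinic with good fertilization
rates likely has good transfer rates); the uniform-PSA design cannot
express such dependence. Outcomes stop at 12-week ongoing pregnancy —
no live-birth, neonatal or long-term horizon.
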