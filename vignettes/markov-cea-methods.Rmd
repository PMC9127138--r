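---
title: "Methods: a three-state Markov cost-utility model for pretreated advanced endometrial cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state Markov cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem

Patients with advanced, recurrent or metastatic endometrial cancer who have
progressed after platinum-based chemotherapy can be treated with lenvatinib
(an oral multikinase inhibitor) plus pembrolizumab (an anti-PD-1 antibody) —
below, "LP" — or with single-agent chemotherapy (doxorubicin or weekly
paclitaxel). LP prolongs progression-free and overall survival but costs an
order of magnitude more per month. `markovcea` implements a cost-utility
model that asks, from a U.S.-payer perspective, whether the survival gain is
worth the price: it computes lifetime discounted costs and quality-adjusted
life-years (QALYs) per strategy, their increments, and the incremental
cost-effectiveness ratio (ICER), judged against a willingness-to-pay (WTP)
threshold of \$100,000/QALY.

## Model structure

The disease process is a cohort-level Markov chain over three mutually
exclusive health states — progression-free (PFS), progressive disease (PD)
and death — with a cycle length of one month. The whole cohort starts in
PFS; PD cannot revert to PFS; death is absorbing. Monthly transition
probabilities are fixed per arm (they were fitted once from the trial's
survival curves and are not sampled in any sensitivity analysis).

"Lifetime" horizon is implemented as 600 monthly cycles. Under every
transition matrix used here more than 99.99% of the cohort has been absorbed
by then; `accumulate()` warns if more than `1e-4` of the cohort is still
alive at the end of the trace, so a scenario with unusually slow absorption
cannot silently truncate its tail.

### Accumulation, discounting, half-cycle correction

Costs accrue as occupancy × monthly state cost; QALYs as occupancy ×
utility × 1/12 year. Both are discounted at 3% per year with
monthly-compounded factors $(1.03)^{-t/12}$ for cycle $t$, and half-cycle
corrected with trapezoidal weights: half weight on cycle 0 and on the final
cycle, full weight elsewhere. This is the standard correction for the fiction
that transitions happen exactly at cycle boundaries; a property test checks
that the corrected total always lies between the cycle-start- and
cycle-end-weighted sums, which bounds the correction's possible effect.

Two kinds of one-time cost are exempt from the half-cycle weighting because
they are event-driven rather than occupancy-driven:

* a **palliative-care cost** (\$11,266.07) charged on each transition into
  death, discounted at the cycle of death and attributed to the cost bucket
  of the state the patient died from (PFS-exit deaths to the PFS bucket, PD
  deaths to the PD bucket) — this attribution best matches the published
  per-state cost decomposition;
* a **dMMR/MSI-H testing cost** (\$666.40) charged once at model entry,
  undiscounted, in both arms. Because it is identical across arms it cancels
  from the increment; a test asserts the ICER is invariant to it.

## Cost composition

Each arm's PFS-state monthly cost is drug acquisition + adverse-event (AE)
management + disease management; its PD-state monthly cost is disease
management + crossover subsequent therapy. All unit inputs are December-2021
U.S. dollars taken as given (price-database lookups and CPI inflation are
outside the package's scope). Arithmetic is kept at full precision and only
rounded at presentation time, half-up to the cent (`round_currency()`).

**Drug acquisition.** LP: lenvatinib \$16,166.98/month (at the trial's
median dose intensity of 13.8 mg/day rather than the labelled 20 mg/day)
plus pembrolizumab \$16,429.87/month. The published acquisition total
(\$32,820.76) exceeds the two drug rows by \$223.91, which the default
configuration carries as intravenous-administration time at \$55.98 per
10 minutes (≈40 min/month) so that the printed total is reproduced to the
cent. The chemotherapy acquisition total (\$765.31) likewise exceeds
doxorubicin (\$164.16) + paclitaxel (\$205.20) by \$395.95; that residual is
an exact multiple of the same \$55.98 administration unit (70.73 min/month)
and is configured the same way. Treating both residuals as administration
time keeps them coupled to the administration-cost parameter in the
sensitivity analyses instead of freezing them as unexplained constants.

**Adverse events.** Grade 3–4 AE management is an incidence-weighted sum of
unit costs, charged monthly while progression-free. The default attribution
is exactly the set that reproduces the published totals to the cent:
hypertension and diarrhea for LP (\$3,611.44/month); anemia, neutropenia,
neutrophil-count decrease and white-blood-cell decrease for chemotherapy
(\$9,614.54/month). Decreased appetite and weight loss occur in the trial's
AE table but have no unit cost row, so they cannot contribute; the
attribution is plain per-arm configuration, not code.

**Crossover subsequent therapy.** With no standard third-line option,
progressed patients are assumed to cross to the other arm's regimen, at
acceptance rates of 28.0% (LP arm) and 48.1% (chemotherapy arm). The monthly
PD cost contribution is acceptance × (other arm's PFS monthly total −
disease management), disease management being already charged in PD. This
linkage is recomputed from components on every model evaluation, so varying
e.g. the LP drug cost automatically moves the chemotherapy arm's crossover
cost — parameters are varied at the unit level, never at the level of
derived rows.

## Health outcomes

Utilities are 0.817 (PFS), 0.779 (PD) and 0 (death), on the EQ-5D scale
where 1 is perfect health; they are shared between arms, so QALY differences
come entirely from occupancy differences. AE disutilities are not modelled
(only AE costs are), consistent with the source analysis.

## From survival medians to transition probabilities

Under an exponential time-to-event assumption a median $m$ months implies a
monthly event probability $P = 1 - 0.5^{1/m}$, equivalently $P = 1-e^{-R}$
with rate $R = \ln 2 / m$. `derive_transitions()` uses this to build a
matrix from a (median PFS, median OS) pair: total PFS exit from the PFS
median, direct PFS→death from the OS median, progression as their
difference, and the PD→death probability either supplied or calibrated by
root-finding so that the model's own median overall survival (the
interpolated cycle at which cumulative survival crosses 0.5) matches the
target, to a tolerance of 1e-6.

The packaged scenarios do **not** use this derivation as the base case: the
published fitted probabilities (e.g. LP PFS-stay 0.911/month) are the
inputs, because they are what produced the published tables. The closed form
serves as an independent audit instead: `validate_transitions()` reports
$|$matrix value − closed form$|$ for both checks. Across all four
arm×population combinations the PFS→death probabilities agree with the OS
medians to within 0.001. The PFS-exit check exposes a genuine inconsistency
in the source inputs: the chemotherapy exit probabilities (0.186 overall,
0.191 pMMR) imply a median PFS of ≈3.3 months, consistent with the 3.2
months the source text states in one place but not with the 3.8 months its
input table lists. The table value (3.8) is kept as the default
configuration and the validator is left to flag the discrepancy rather than
hiding it; tests assert both the flag and the agreement with the
alternative 3.2-month reading.

## Sensitivity analysis

**One-way (tornado).** Each parameter is set to its published low and high
value (±25% of base where no range is printed) with everything else at
base, the full deterministic model is rerun, and parameters are ranked by
ICER swing. The two drug rows of an arm are varied jointly as a single
"drug acquisition" parameter — the combination price is one decision
variable (a payer cannot discount lenvatinib and pembrolizumab
independently of the regimen), and it is how the source reports its most
influential factor. Derived rows (acquisition totals, subsequent therapy)
are never varied directly; they recompute from the varied units.

**Probabilistic (PSA).** 10,000 draws; each draw samples every non-Fixed
parameter independently — Gamma for costs, Beta for utilities, by the
method of moments with mean equal to the base value — reruns both arms, and
records per-draw discounted costs and QALYs. Transition probabilities are
Fixed and never sampled. The acceptability curve (CEAC) reports, per WTP
value, the fraction of draws with positive incremental net monetary benefit
$\mathrm{NMB} = \mathrm{WTP}\times\Delta\mathrm{QALY} - \Delta\mathrm{Cost}$.
One seed (default 20220510) governs the whole PSA; results are reproducible
bit-for-bit given the seed, and the caller's RNG state is restored.

The published ranges carry no stated distribution hyper-parameters, so the
spread assigned to them is a modelling choice exposed as
`run_psa(range_z = )`: the default reads a (low, high) range as a 95%
interval, `sd = (high - low)/3.92`. Reading the ranges as mean ± 1 SD
(`range_z = 1`) instead reproduces the spread of the published Monte-Carlo
summaries (a test asserts the LP QALY SD then comes out at ≈0.25); the
default is kept at the conventional 95% reading because the PSA *means* and
the CEAC crossing point — the decision-relevant quantities — are unaffected
by the choice, both readings being mean-preserving.

Because the transition matrices are fixed, the cohort traces are computed
once and reused across all tornado runs and PSA draws; only the state
valuations are recomposed per evaluation. A full 10,000-draw PSA runs in
well under a minute on one core.

## Synthetic patient-level data

The engine consumes published summaries, not patient-level data, so the
synthetic-data module exists to *stress* the survival-input pathway, not to
feed the base case. `simulate_ipd()` draws progression times exponential
with rate $\ln 2/m_\mathrm{PFS}$ and adds an independent exponential
post-progression time whose rate is solved numerically so the marginal OS
median matches $m_\mathrm{OS}$ — the simplest structure consistent with the
three-state model. Optional independent exponential censoring exists only to
stress the Kaplan–Meier stand-in (`km_from_ipd()`, a thin wrapper over
`survival::survfit()` that emits the two-column points a curve digitizer
would produce); the default is no censoring. What these data do **not**
emulate: non-constant hazards (the real trial's KM curves are not
exponential), covariates, arm-level recruitment, or any reconstruction of
actual trial patients. Passing the round-trip tests (fitted rate within 10%
of $\ln 2/7.2$ at $n=500$; median of fitted rates within 3% over 100 seeds)
therefore validates the estimation pathway under the model's own
assumptions, not the exponential assumption itself.

`random_scenario()` generates fully valid random two-arm scenarios
(row-stochastic matrices with absorbing death, non-negative costs, utilities
in [0, 1]) for property sweeps: occupancy conservation, death absorption,
and end-to-end runnability of every analysis stage are tested across seeds.

## Numerical choices and degenerate inputs

* Transition-matrix rows must sum to 1 within 1e-6 (printed inputs carry
  three decimals) and are renormalised to sum exactly; after that, traces
  conserve occupancy to 1e-10 per row.
* Probability 1 → rate conversion is an error (infinite rate), as is a
  non-positive median.
* `fit_exponential()` drops survival-0 points (uninformative on the log
  scale) and refuses all-survival-1 input as non-identifiable.
* PD→death calibration brackets before root-finding and fails loudly when
  the target median OS is unreachable.
* Beta fitting clips the variance below `m(1-m)` when a stated range is too
  wide for the support; sampled utilities are clipped into [0, 1] with a
  logged count (the packaged scenarios never trigger either).
* An equal PFS and OS median routes the whole PFS exit to death
  (progression probability floored at 0, with a warning when the floor
  actually binds).

## Problem sizes

The packaged analyses use the study conditions throughout: 600-cycle
horizon, 10,000 PSA draws, ±25% one-way ranges, WTP \$100,000/QALY. Property
sweeps use 25 random scenarios for trace invariants, 3 for full end-to-end
runs (at 40 PSA draws), and 100 seeded cohorts of 500 patients for
exponential-rate recovery; these sizes give stable verdicts for the
invariants they check while keeping the default test run fast.

## Known limitations

* Three states, constant monthly transition probabilities: no time-varying
  hazards, tunnel states or individual-level microsimulation. The published
  per-state results are reproduced to ≈0.2%, but the source tool's exact
  accumulation scheme is not documented, which is why the package's own
  acceptance checks use a 5% band rather than cent-exactness for cohort
  totals (cent-exactness applies to the monthly cost arithmetic, which is
  fully specified).
* Parameters are sampled independently in the PSA; no correlation structure
  is available in the source to do better.
* The crossover assumption (progressed patients receive the other arm's
  regimen at fixed acceptance rates) is structural; alternative
  subsequent-therapy patterns require editing the scenario, not the code.
* Cost inputs are U.S.-payer, December-2021; transferring the scenario to
  another setting means replacing the cost section wholesale.
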