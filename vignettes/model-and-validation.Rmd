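---
title: "The decision model, its calibration, and how it is validated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The decision model, its calibration, and how it is validated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vteprophy)
```

## The decision problem

Acutely ill medical inpatients are at substantial risk of venous
thromboembolism (VTE): deep vein thrombosis (DVT) and its potentially
fatal sequela, pulmonary embolism (PE). Guideline-recommended
pharmacological prophylaxis — low-molecular-weight heparin (LMWH,
enoxaparin 40 mg once daily) or unfractionated heparin (UFH, 5000 IU
twice daily), each for seven days — reduces that risk at the price of
drug adverse events (bleeding, heparin-induced thrombocytopenia, HIT)
and drug cost. `vteprophy` implements a 30-day decision-tree model that
weighs these against each other for a hypothetical cohort of 10,000
at-risk medical inpatients, from a US healthcare-system perspective in
2013 US$, and then asks what full guideline adherence would mean at the
scale of the US acute-care system.

The model deliberately stops at 30 days and at death/cost endpoints: no
QALY weighting, no multi-cycle (Markov) extension, and — because the
horizon is short — no discounting.

## Tree structure

Every patient enters at hospital admission and is routed through:

1. **Prophylaxis adverse events** (active strategies; the no-prophylaxis
   arm carries a small background bleed risk). Bleed and HIT are
   mutually exclusive first-level events. Bleeds split into major
   (possibly fatal) and minor; HIT into symptomatic (possibly fatal) and
   asymptomatic. Survivors of a drug adverse event are assumed to face
   no further VTE risk — a simplification that makes AE risk purely a
   cost of prophylaxis.
2. **Incident DVT** (probability per strategy — this is where
   prophylaxis efficacy enters). A DVT is only treated if it is
   clinically suspected (sensitivity 0.657) *and* confirmed on
   ultrasound (sensitivity 0.960); treatment carries the workup and
   treatment costs, its own bleed/HIT risks (reusing the shared severity
   subtrees), and a residual PE risk of 0.018. Unsuspected or
   unconfirmed DVT goes untreated, with a much larger PE risk (0.511 at
   base case).
3. **Pulmonary embolism.** One tenth of PE episodes end in sudden death
   before any care can be delivered (no costs accrue). Surviving
   episodes pass a clinical-suspicion gate (sensitivity 0.291) and a
   confirmatory scan (the average of CT and ventilation/perfusion
   performance, sensitivity 0.585); confirmed PE is treated (fatality
   0.015), undiagnosed PE is not (fatality 0.260).
4. **False positives.** Non-DVT patients can be false clinical positives
   for DVT (1 − specificity 0.869), paying the workup cost, and false
   ultrasound positives on top (1 − 0.962), paying treatment cost and
   treatment-AE risk. Symptomatic monitoring of the DVT pathway also
   produces false-positive PE workups among patients who do not develop
   PE, with a small treatment fatality (0.003) for the doubly false
   positive.
5. **Underlying illness.** Every patient who has not died of a modelled
   cause faces a terminal, competing 0.100 probability of dying of the
   underlying medical condition. This branch dominates the absolute
   death counts and is identical across strategies.

Each strategy tree has 87 terminal paths; the count is frozen as a
regression constant in the tests.

### Interpretation choices the sources left open

The published account of this model class fixes the probability of every
branch but not every structural detail. The choices below were made
once, on calibration against all six base-case outputs (three death
counts and three cost totals), and are part of the model definition:

* **PE case fatalities are unconditional episode proportions.** The
  treated (0.015) and untreated (0.260) PE fatality parameters are read
  as proportions of *all* PE episodes, additional to the 10% sudden
  deaths. Inside the tree, the branch probability conditional on
  surviving the immediate window is therefore `p / (1 − p_sudden)`.
  Under the alternative (conditional) reading the model under-predicts
  prophylaxis benefit by roughly 7%.
* **False-positive PE workups arise in the DVT pathway only.** Extending
  them to every non-DVT patient adds about $140 per patient to the
  no-prophylaxis arm and is grossly incompatible with the published cost
  totals.
* **Treatment adverse events can be fatal** and reuse the same severity
  subtrees and costs as prophylaxis adverse events; deaths there are
  attributed to a distinct cause (`dvt_tx_ae`).
* **Sudden PE death bypasses all diagnosis and treatment costs**;
  diagnosed fatal PE still accrues them (costs attach to services
  rendered).
* **Residual PE risk after DVT treatment applies to the AE-free branch**,
  consistent with the AE-survivor simplification above.

With these choices the base case lands within 0.35% of all six published
figures (deaths 1086.7 / 1039.5 / 1055.3 per 10,000 for no prophylaxis /
LMWH / UFH, against printed 1087 / 1040 / 1057), without any fitted or
free parameter: every number in the tree is a published point estimate.

## Parameters

All parameters live in a single YAML file
(`system.file("extdata", "params_default.yaml", package = "vteprophy")`),
organised to mirror the source tables: per-strategy efficacy/safety
probabilities and 7-day drug costs; shared event, natural-history and
diagnostic probabilities; unit costs in 2013 US$; and the population
constants (survey funnel counts, the 14.3 million national denominator,
the 51.1% at-risk fraction and its 44.8–62.2% between-hospital
interquartile range). `load_parameters()` validates every structural
invariant — probabilities in [0, 1], AE exclusivity, the structural zero
HIT risk without drug exposure, non-negative costs, monotone funnel
counts — and recomputes the averaged-scan sensitivity/specificity from
the CT and V/Q rows rather than trusting the stored average. Any subset
of keys can be overridden from a user file; the rest fall back to the
shipped defaults.

```{r basecase}
bundle <- default_parameters()
basecase_table(bundle)
```

## Three evaluation routes

The same tree is evaluated three mutually independent ways, and the
tests require them to agree:

* `evaluate_tree()` — recursive analytic expectation (the production
  route; exact up to floating point);
* `enumerate_paths()` — exhaustive path listing whose probabilities must
  sum to 1 within 1e-10 and whose expectation must match the recursion
  within 1e-9 relative;
* `simulate_cohort()` — a patient-level microsimulation twin that walks
  a million synthetic patients through the tree and must land within
  3 standard errors of the analytic death rate and mean cost for every
  strategy.

## Sensitivity analyses

**One-way scans and thresholds.** `one_way_scan()` rebuilds the whole
model at each grid value of a single parameter. `find_threshold()`
bisects a named criterion (cost-saving, death-averting, or both, for one
or both strategies versus no prophylaxis) to a configurable tolerance,
refusing non-monotone configurations instead of answering silently; a
dense-grid oracle cross-checks the bisection in the tests. Two
criterion families matter for the classic threshold question on
p(PE | untreated DVT): in this reconstruction both strategies remain
*cost-saving* over the entire (0, 0.511) range — the criterion never
crosses — while the *death-averting* (and hence jointly dominant)
criterion crosses at ≈ 0.129, with UFH binding (its adverse-event deaths
need ≈ 13% untreated-DVT PE risk to be offset). The published threshold
statement (14%) is reproduced in direction and binding strategy but not
to the percent; the gap traces to the same small
incremental-quantity sensitivities discussed under *Limitations*.

**Probabilistic sensitivity analysis.** `run_psa()` redraws every
probability from a beta distribution (`α = p·n`, `β = (1−p)·n`) and
every cost from a gamma distribution (`shape = 1/cv²`,
`scale = mean·cv²`), rebuilds the three trees and re-evaluates, 10,000
iterations by default. The sources publish the distribution families but
not their spreads, so the defaults are the package's own and are fully
overridable: effective sample size 300 for event probabilities (the
scale of the pivotal prophylaxis-trial arms), 1000 for diagnostic
sensitivities/specificities (pooled imaging studies), and cv = 0.25 for
costs (typical reimbursement heterogeneity). Structural zeros (the HIT
probability without drug exposure) are never sampled; the averaged-scan
rows are recomputed from the sampled CT and V/Q draws; parameters are
drawn independently (no correlation structure is published). One master
seed deterministically derives per-iteration seeds, so runs are
bit-reproducible end to end. Consequences of these choices: percentile
bands straddle the base case (asserted as an ordering property, not as
numeric targets, precisely because the spreads are not published), and
LMWH — dominant at base case — stays optimal in well over half the
iterations.

**Acceptability curves.** `build_ceac()` ranks strategies per iteration
by net monetary benefit `λ × deaths averted − incremental cost` with no
prophylaxis as the zero-benefit reference, breaking ties toward the
cheaper strategy; fractions across strategies sum to 1 at every
willingness-to-pay value.

## National extrapolation

The survey funnel (9257 enrolled → 5196 medical ward → 2720 at
ACCP-defined VTE risk → 1292 receiving recommended prophylaxis; 331 of
the at-risk contraindicated) is kept as printed integers; every
percentage is derived as an exact ratio. The national chain multiplies
the 14.3 million eligible medical discharges by the 0.511 at-risk
fraction (the survey's patient-weighted figure, which reproduces the
printed 7.3 million; the unweighted 52.3% stage ratio is also available
in the config), removes the 47.5% already protected, excludes the 12.2%
contraindicated, and scales the unrounded cohort deaths-averted rate up
to the resulting ≈ 3.37 million eligible-but-unprotected patients.
Per-1%-adherence figures are exactly the totals divided by 100, and the
between-hospital scenario reruns the chain at the 44.8% and 62.2%
at-risk endpoints. All arithmetic is unrounded; rounding happens only in
the report writers (deaths to integers, dollars to whole US$,
percentages to one decimal). Note one internal inconsistency of the
source narrative: its prose quotes "total" savings that match the
per-1% figures; the implementation follows the tabulated totals
(per-1% × 100) and does not repair the prose silently.

## The synthetic admission generator

`generate_admissions()` emulates just enough of a national discharge
sample to exercise the eligibility filters end to end: age (truncated
normal, mean 65, sd 15), length of stay (1 + geometric, mean 5 days), an
operating-room flag, a single at-risk diagnosis flag standing in for the
ten guideline diagnosis categories (a category label is carried for
realism but never branched on), and contraindication/prophylaxis flags.
The marginals are independent — no hospital clustering, survey
weighting, ICD-9 coding, or age–risk correlation — so passing filter
tests demonstrates that the inclusive thresholds (age ≥ 40 years, stay
≥ 2 days, no operating room) and the funnel tabulation are correct, not
that the generator is demographically realistic.

## Numerical choices

Branch probabilities must sum to 1 within 1e-12 at every internal node
(checked on every evaluation, not only at construction); path
probabilities to 1e-10; the two analytic routes to 1e-9 relative.
Bisection runs to an absolute tolerance of 1e-4 (1e-5 in the acceptance
script) after a 9-point monotonicity screen. Default problem sizes —
10,000-patient cohort, 10,000 PSA iterations, one-million-patient
microsimulation — evaluate in seconds to about a minute on a single
core; a single tree evaluation is ~2 ms.

## Limitations

* The tree topology is a calibrated reconstruction: the published
  account fixes all probabilities but not every structural placement.
  Absolute outcomes reproduce to a few tenths of a percent, but UFH's
  incremental quantities are differences between two ~$13M totals, so
  sub-percent absolute errors inflate to several percent there (UFH
  incremental cost −$727k here vs −$771k published; the corresponding
  cost-per-death-averted and national UFH projections inherit the gap,
  as does the threshold percentage above). The LMWH incremental
  quantities agree to ~0.3%.
* Published cost-per-death-averted figures divide incremental cost by
  the *integer-rounded* deaths averted; the package keeps the unrounded
  ratio and leaves rounding to the report layer.
* PSA spreads are the package's own defaults (see above), so Monte
  Carlo percentile rows are checked only as ordering properties.
* All the usual limits of the source model apply: 30-day horizon, no
  long-term sequelae, one admission = one exposure when annualising,
  Medicare/wholesale prices as cost proxies.
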