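# vteprophy

Decision-tree cost-effectiveness analysis of pharmacological venous
thromboembolism (VTE) prophylaxis in acutely ill medical inpatients,
from a US healthcare-system perspective.

Hospitalized medical patients are at high risk of deep vein thrombosis
(DVT) and pulmonary embolism (PE), and guideline-recommended
anticoagulant prophylaxis remains widely underused. This package is for
health-economics and outcomes researchers who want a fully reproducible,
testable implementation of the standard 30-day decision-analytic
argument for closing that gap: it quantifies deaths and costs under
low-molecular-weight heparin (LMWH, enoxaparin 40 mg qd), unfractionated
heparin (UFH, 5000 IU bid) and no prophylaxis, and projects the results
to the US national inpatient population.

## The model

A 30-day decision tree for a cohort of 10,000 at-risk medical
inpatients. For strategy *s* with DVT risk `p_dvt(s)`, adverse-event
risks `p_bleed(s)`, `p_hit(s)` and 7-day course cost `c(s)`:

* drug adverse events come first (bleed → major/minor, HIT →
  symptomatic/asymptomatic; major bleeds and symptomatic HIT can kill;
  AE survivors face no further VTE risk);
* DVT is treated only when clinically suspected **and**
  ultrasound-confirmed; untreated DVT progresses to PE with probability
  0.511, treated DVT with 0.018;
* PE kills suddenly with probability 0.10; surviving episodes are
  diagnosed through a clinical gate and an averaged CT/V-Q scan, with
  case fatality 0.015 treated and 0.260 untreated;
* false-positive DVT and PE workups incur real costs (and a small
  treatment mortality);
* everyone else faces a competing 0.10 risk of dying of the underlying
  illness.

Expected deaths `D(s)` and costs `C(s)` come from exact probability
roll-forward of the tree; strategies are compared by the incremental
cost-effectiveness ratio

```
ICER(s) = (C(s) − C(none)) / (D(none) − D(s))      [$ per death averted]
```

with negative values meaning the strategy saves both lives and money
(dominance). One-way threshold analysis (bisection), probabilistic
sensitivity analysis (beta/gamma parameter distributions, 10,000 Monte
Carlo iterations) and cost-effectiveness acceptability curves quantify
parameter uncertainty. A survey-derived eligibility funnel (9257 → 5196
medical ward → 2720 at risk → 1292 protected; 331 contraindicated)
applied to the 14.3 million eligible US discharges scales the cohort
results to national annual impact. Every parameter ships in one
human-editable YAML file and can be overridden key by key.

## Worked example

```r
library(vteprophy)

bundle <- default_parameters()
outcomes <- lapply(build_all_trees(bundle), evaluate_tree, cohort_size = 10000)
outcomes$NONE
#> NONE cohort of 10000: 1086.7 expected deaths, total cost $13,689,806
outcomes$LMWH
#> LMWH cohort of 10000: 1039.5 expected deaths, total cost $11,306,648

cea <- compare_strategies(outcomes$LMWH, outcomes$NONE)
cea
#> LMWH vs NONE: incremental cost $-2,383,158, 47.2 deaths averted (dominant)
#>   cost per death averted: $-50,485
```

Per 10,000 patients, LMWH prophylaxis prevents ~47 of the ~1087 30-day
deaths expected without prophylaxis (a 0.5 percentage-point reduction)
while *saving* about $2.4M — roughly $50k saved per death averted, i.e.
a dominant strategy. Scaling to the eligible-but-unprotected national
population:

```r
rates <- funnel_rates(bundle$population$endorse_counts)
funnel <- apply_funnel(bundle$population$nis_eligible_total,
                       bundle$population$at_risk_fraction,
                       rates[["receiving_rate"]],
                       rates[["contraindicated_rate"]])
national_impact(funnel$eligible_unprotected, cea)
#> LMWH: 15906 deaths averted/year nationally, $803,001,440 saved
#>   (159 and $8,030,014 per 1% adherence gain)
```

The report commands write the same quantities as CSV plus
display-rounded text tables (`cmd_basecase()`, `cmd_psa()`,
`cmd_extrapolate()`; a thin CLI wrapper lives in `inst/cli/`):

```
Cost-effectiveness at base case (cohort of 10000)
            Strategy  Total cost Deaths Incremental cost Deaths averted Cost/death averted
      No prophylaxis $13,689,806   1087                -              -                  -
 Enoxaparin 40 mg qd $11,306,648   1039      -$2,383,158             47           -$50,485
     UFH 5000 IU bid $12,962,607   1055        -$727,199             31           -$23,163
```

See `vignettes/model-and-validation.Rmd` for the model's assumptions,
the calibration of the tree topology, the PSA spread defaults, and known
limitations (in particular, UFH's incremental quantities are small
differences of large totals and are the least stable outputs of the
reconstruction).

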