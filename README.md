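# cltriage

Cervical-length screening triage for pregnancies after cervical conization.

Women treated for cervical intra-epithelial neoplasia by excisional surgery
(cone biopsy, LLETZ, LEEP) carry an elevated risk of preterm birth in a
subsequent pregnancy and are followed in preterm-surveillance clinics with
serial second-trimester transvaginal cervical-length (CL) measurements at
three visits — A: 13+0–15+6, B: 16+0–18+6, C: 20+0–22+6 weeks — with
ultrasound-indicated cerclage offered when the cervix shortens below 25 mm
before 24 weeks. Most of these pregnancies nevertheless deliver at term, so
much of the scanning effort is spent on women who never needed it.

`cltriage` is an R implementation of the analysis pipeline for this setting,
built for clinical epidemiologists who want to reproduce, stress-test or
extend the approach on their own cohorts:

* **Cohort model** — gestational-age arithmetic (`"W+D"` notation),
  eligibility filtering, the GROUP1/GROUP2 outcome stratification
  (GROUP2 = preterm birth < 37+0 weeks and/or cerclage), interval
  percentage CL change `%ΔCL = 100 (CL_early − CL_late) / CL_early`
  (positive = shortening) from pre-cerclage measurements only, and a
  documented CSV interchange format (`read_cohort()` / `write_cohort()`).
* **Sequential triage model** (`triage_model()`, `run_triage()`) — a fixed
  three-step rule set that classifies each visit as high-risk, discharge, or
  continue. Defaults: high at A if CL < 19 mm, discharge if ≥ 42 mm; at B
  high if CL < 23 mm or ΔCL(A–B) ≥ 21 %, discharge if CL ≥ 38 mm or
  ΔCL(A–B) < 6 %; at C high if (CL_A < 28 mm and ΔCL ≥ 5 %) or CL_C ≤ 24 mm
  or (CL_A ≥ 24 mm and CL_B < 26 mm), otherwise discharge.
* **Constrained derivation** (`derive_triage_model()`) — rebuilds such a
  model from a labelled cohort: exhaustive threshold grid searches for steps
  A and B maximising resolved records subject to a discharge-safety
  constraint (GROUP2 share among cumulative discharges ≤ 5 %), a Gini
  recursive-partitioning third step, and leave-one-hospital-out validation.
* **Diagnostic accuracy** (`sweep_cl()`, `sweep_delta()`, `roc_curve()`) —
  Se/Sp/PPV/NPV and the positive likelihood ratio Se/(1−Sp) for CL ≤ t and
  ΔCL ≥ d predicates, always from unrounded counts.
* **Contingency statistics** (`relative_risk()`, `fisher_exact()`,
  `mann_whitney()`, `kruskal_wallis()`) — Katz log-normal confidence
  intervals, the small-p two-sided exact test, rank tests with exact
  small-sample enumeration.
* **Scan accounting** (`scan_savings()`) — follow-up scans avoided under a
  triage policy.
* **Synthetic cohort generator** (`cohort_config()`, `generate_cohort()`) —
  a calibrated simulator of the four outcome subgroups (581 term births
  without cerclage, 46 preterm without, 24 preterm with, 74 term with
  cerclage) with truncated-normal CL trajectories, per-visit missingness,
  forced short-CL visits for cerclage recipients and post-cerclage
  censoring, so every downstream stage is testable without clinical data.

Everything is tidyverse-shaped: cohorts are tibbles (one row per
pregnancy), results are tibbles, fitted models support `tidy()` /
`glance()`, and sweep/ROC results have `autoplot()` methods.

## Worked example

```r
library(cltriage)

cohort <- generate_cohort(cohort_config(seed = 2016)) |> add_risk_group()
outcomes <- run_triage(cohort, triage_model())
dplyr::count(outcomes, exit_timepoint, final)
#>   exit_timepoint final         n
#> 1 A              DISCHARGE    17
#> 2 A              HIGH_RISK    11
#> 3 B              DISCHARGE   300
#> 4 B              HIGH_RISK    35
#> 5 C              COMPLETED   307
#> 6 C              HIGH_RISK    55
```

Of 725 simulated women, 28 leave surveillance at the first visit and 335
more at the second; 307 complete all three scans and are discharged there
(`COMPLETED`), while 101 are flagged high-risk at some visit. In scans:

```r
scan_savings(outcomes)[, c("scans_avoided", "scheduled_followups",
                           "pct_followups_avoided")]
#>   scans_avoided scheduled_followups pct_followups_avoided
#> 1           391                1450                  27.0
```

so 27% of the 1450 scheduled follow-up scans would not have happened under
the triage policy. The suture-material comparison on the same cohort:

```r
sc <- suture_comparison(cohort)
sc$rates
#>   suture           n preterm preterm_pct
#> 1 monofilament    61      11        18.0
#> 2 braided         37      13        35.1
sc$rr_term_braided_vs_mono
#> RR 0.79, 95% CI 0.61 to 1.03
```

and a threshold sweep at the first visit, with the display columns rounded
the way such tables are reported (integer percents, LR to one decimal):

```r
as.data.frame(sweep_cl(cohort, "A")[, c("threshold", "s_pct", "sp_pct",
                                        "ppv_pct", "npv_pct", "lr_1dp", "n")])
#>   threshold s_pct sp_pct ppv_pct npv_pct lr_1dp   n
#> 1        20    10    100     100      80    Inf 613
#> 2        25    39     98      85      86   21.1 613
#> 3        30    62     78      44      89    2.9 613
#> 4        35    82     35      25      88    1.3 613
#> 5        40    93      7      21      78    1.0 613
#> 6        50   100      0      21     100    1.0 613
```

Low CL thresholds are highly specific but insensitive; sensitivity improves
(and specificity collapses) as the threshold rises — the pattern that
motivates a sequential triage rule instead of a single cut-off.

`run_pipeline(out_dir = "run1", seed = 1)` chains all of the above and
writes each table as CSV plus a JSON manifest; a thin command-line wrapper
with verbs `simulate` / `triage` / `derive` / `sweep` / `stats` / `report`
is installed at `inst/scripts/cltriage.R`.

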