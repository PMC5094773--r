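---
title: "Methods: cervical-length triage after conization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cervical-length triage after conization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cltriage)
```

This vignette is the package's account of its own methods: the screening
model and its assumptions, the derivation procedure, what the synthetic
cohort generator does and does not emulate, and the numerical conventions
that make results reproducible. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The clinical setting and the outcome stratification

After excisional treatment for CIN, pregnancies are followed with serial
transvaginal cervical-length (CL) measurements in three second-trimester
windows — A: 13+0–15+6, B: 16+0–18+6, C: 20+0–22+6 weeks — under a protocol
that offers ultrasound-indicated cerclage when CL drops below 25 mm before
24 weeks. Gestational ages are handled internally as total days
(`7 * weeks + days`); the preterm boundary is strict: preterm means
< 37+0 weeks, i.e. < 259 days, so 36+6 is preterm and 37+0 is term.

The analysis stratifies outcomes into GROUP1 (term birth, no cerclage) and
GROUP2 (preterm birth and/or cerclage). GROUP2 is the positive class of
every accuracy computation in the package. Two consequences of keying the
definition on cerclage *insertion* are worth making explicit:

* a woman who reached the CL threshold but declined cerclage is GROUP2 only
  if she delivered preterm; she stays eligible and carries a
  `declined_cerclage` flag;
* GROUP2 splits into three subgroups (preterm without cerclage, preterm
  with, term with) that, with GROUP1, partition the cohort — a property the
  tests assert.

Interval shortening is `%ΔCL = 100 (CL_early − CL_late) / CL_early`, the
denominator always the earlier measurement, positive values meaning
shortening. Only pre-cerclage measurements enter any `%ΔCL` or summary
cell: a measurement at a visit whose window opens after the recorded
insertion gestation is censored (`censor_post_cerclage()`); the visit that
triggered the insertion is itself pre-cerclage and is kept.

## The sequential triage model

`triage_model()` holds eleven thresholds. At each visit the high-risk rule
is evaluated before the discharge rule — safety-first precedence, so a
record satisfying both is called high-risk. Missing data semantics: a
clause whose operand is missing is inert (it cannot fire), and a wholly
missed visit yields `CONTINUE`, so a woman is never discharged or flagged
on evidence she does not have. Step C is terminal: anything not called
high-risk there is discharged (`COMPLETED`).

Two points in the published rule set are ambiguous, and both are exposed as
arguments rather than silently resolved:

* **The step-B discharge rule is a disjunction as printed** ("CL ≥ 38 mm
  *or* shortening < 6 %"). Taken literally this discharges a cervix that is
  short but stable — e.g. 24 mm at A and B shortens 0 % < 6 %. We implement
  the printed disjunction as the default and provide
  `b_low_rule = "and"` as the conservative conjunctive variant.
* **The step-C "≥ 5 % shortening" interval is unstated.** We default to
  A–C, the longest interval and the one using the same anchor (CL at A) as
  the rest of the step-C rule; `c_rule1_delta_interval = "B-C"` is
  available.

## The derivation procedure

`derive_triage_model()` rebuilds the three-step model from a labelled
cohort under a discharge-safety constraint: the share of GROUP2 women among
all discharge calls accumulated so far must stay at or below
`max_false_low_risk_rate` (default 5 %). An alternative reading of "5 %" —
discharged GROUP2 women as a share of all GROUP2 women — is available via
`constraint_scope = "group2_share"`.

* **Steps A and B** are exhaustive grid searches (integer mm over 10–50,
  integer percent over 0–40, covering every published threshold) maximising
  the number of records resolved (high + discharged). Step B searches the
  full threshold quadruple with counts taken from 2-D cumulative
  histograms, so each candidate is O(1); the search respects the model
  invariant that the discharge CL threshold exceeds the high one. The
  step-A search is verified against a brute-force enumeration oracle in the
  tests.
* **Tie-breaking** is conservative and deterministic: among equal-objective
  candidates, prefer the smallest discharge region (largest discharge
  threshold), then the smallest high-risk region. These tie-breaks are what
  make threshold recovery well-defined on a cohort with an empty CL gap
  between the groups: the recovered thresholds land on the gap edges, which
  the planted-recovery tests exploit.
* **A known degeneracy, kept deliberately.** The stated objective
  constrains only the discharge side, so on overlapping cohorts nothing
  stops the high-risk region from absorbing every unresolved record when
  that raises the count. We implement the objective as stated, and offer an
  optional symmetric purity constraint (`max_false_high_risk_rate`,
  default off) for users who want clinically interpretable models from
  overlapping data.
* **Step C** fits a recursive-partitioning classifier with Gini impurity on
  CL at A/B/C and the three interval changes, depth ≤ 3 and leaf size ≥ 10,
  using rpart with `cp = 0` and no surrogate or competitor splits. Leaves
  are then discharged greedily in order of GROUP2 purity while the
  cumulative constraint holds; leaves tied on purity are admitted or
  refused together. Prediction recovers leaf membership through the leaf's
  training purity (the predicted class probability of a tree equals the
  leaf fraction), which makes the labelling robust to leaf renumbering. If
  only one outcome class reaches step C the stage degenerates to a single
  labelled leaf. Fig-3-shaped thresholds are read off the tree's primary
  splits where the structure allows, for interpretability; prediction uses
  the tree itself.
* **Validation** is leave-one-hospital-out: derive on the other sites,
  evaluate on the held-out site, reporting GROUP2 sensitivity and the
  false-low-risk rate (GROUP2 share among low-risk calls) per fold.

## Diagnostic accuracy conventions

Each sweep row uses only records with the required measurement(s) observed
(per-row denominators, as longitudinal missingness dictates). All metrics
are computed from unrounded counts; the display columns round percentages
to integers and the likelihood ratio to one decimal, but the likelihood
ratio is always Se/(1−Sp) of the *unrounded* values — rounding first can
distort it severely at high specificity. An empty test-negative cell that
misses no positives renders NPV as 100 % by convention (symmetrically for
PPV), with the internal value kept `NA` and flagged. ROC curves enumerate
every distinct observed threshold plus both corner points, and the AUC is
the trapezoid rule; the construction is cross-checked against pROC in the
tests.

## Contingency and rank statistics

* `relative_risk()` uses the Katz log-normal interval with
  `z = qnorm(0.975) = 1.959964`; the unrounded quantile matters for
  reproducing two-decimal interval endpoints stably. A zero event cell
  leaves the interval undefined unless the 0.5 continuity correction is
  requested (flagged in the result).
* `fisher_exact()` implements the "small-p" two-sided rule — sum the
  hypergeometric probabilities of all tables no more probable than the
  observed one — summing in ascending order with a 1e-7 relative tolerance
  for ties; it is checked against the reference implementation over
  thousands of random tables.
* `mann_whitney()` enumerates all group assignments exactly when both
  sides have at most 8 observations (valid under ties, unlike the standard
  exact path) and otherwise uses the tie-corrected normal approximation
  without continuity correction; for two groups the Kruskal–Wallis H equals
  the square of that z, an identity the tests verify.

## The synthetic cohort generator

No patient data ship with the package; the generator emulates the cohort
*structure* so every stage is testable.

* **Subgroup design.** Four subgroups with default sizes 581 / 46 / 24 / 74
  and first-visit CL means (SD) of 33.6 (4.2), 32.3 (6.0), 26.8 (5.4) and
  25.8 (5.4) mm. Longitudinal dependence is induced multiplicatively:
  per-record shortening fractions f(A–B) and f(B–C) are drawn from
  truncated normals (bounds −50 % to 95 %) with subgroup-specific means —
  3/4/18/12 % for A–B and 2/6/39/30 % for B–C — and CL at B and C follow as
  `CL_B = CL_A (1 − f_AB/100)` clipped to 5–60 mm, etc. This makes the
  interval `%ΔCL` moments the direct calibration targets; the emergent CL
  means at B and C are documented, not asserted, except for their ordering
  across subgroups, which is tested.
* **Missingness** is per-visit Bernoulli, calibrated for visit A to the
  bracketed cell counts of the source subgroup tables (e.g. 481/581 for the
  term-no-cerclage subgroup); records losing all three visits have their
  missingness pattern redrawn, because the study includes only women with
  at least one measurement. For cerclage subgroups the B/C cell counts are
  dominated by post-insertion censoring, so their base missingness is a
  nominal 10 % and the observed cell sizes are emergent.
* **Cerclage subgroups** must, by protocol, show an observed visit with
  CL < 25 mm; trajectories (with their missingness) are redrawn until one
  exists. This conditioning shifts the first-visit CL marginal slightly
  downward; the acceptance tests compare the realised mean against a
  numerical-integration oracle that integrates the conditioning over
  (CL_A, f_AB, f_BC) and the missingness patterns, rather than against the
  unconditioned truncated-normal mean. Insertion is at the first observed
  short visit; the gestation at insertion is uniform within that visit's
  window; later visits are censored.
* **Gestation at birth** is truncated normal per subgroup, in weeks:
  39.1 ± 1.8 on [37, 42] for term-no-cerclage; both cerclage subgroups use
  the pooled suture-group distribution 38.0 ± 3.1 truncated at 37 weeks
  (below for the preterm subgroup, above for the term one), so preterm
  subgroups deliver before 37+0 by construction. For preterm births without
  cerclage no distribution is printed anywhere; we chose 34.0 ± 2.5 weeks
  on [24, 36+6], a late-preterm-skewed shape typical of this population.
* **Suture material** is assigned conditionally on outcome by default
  (monofilament with probability 9/24 among preterm and 51/74 among term
  cerclage deliveries), reproducing both the 60/38 marginal split and the
  reported suture–outcome association in expectation; outcome-independent
  assignment by the marginal split is available.
* **Demographics** (age, BMI, parity, ethnicity, smoking at 7 % vs 23 % by
  risk group) are descriptive fill sampled independently of CL. The
  generator does **not** model gestational-age-dependent CL percentile
  curves, covariate effects on shortening (smoking is independent of CL by
  design), within-sonographer correlation, or cerclage treatment effects on
  subsequent CL. Passing tests on synthetic data therefore demonstrate the
  correctness of the *pipeline machinery*, not clinical validity on real
  cohorts.
* **Determinism.** Truncated normals are sampled by inverse CDF on the
  truncated interval, so the cohort is a deterministic function of the
  configuration seed; identical config and seed give identical cohorts
  byte for byte, which the pipeline tests assert.

## Problem sizes and runtime posture

The property suites run on cohorts of about 10,000 records (the default
subgroup mix scaled 14×) for triage totality and sweep identities, 10,000
per subgroup for generator calibration, 2,000 records across three
hospitals for derivation recovery, 1,000 random tables for the exact-test
equivalence, and 10,000 simulated binomial pairs for Katz interval
coverage. These sizes give Monte-Carlo standard errors comfortably inside
the asserted tolerances (e.g. 0.2 mm for a CL mean with SD ≈ 4–5 mm at
n = 10,000) while keeping the whole suite fast.

## Known limitations

* The derivation objective reproduces the stated procedure including its
  degeneracy on overlapping cohorts (see above); derived models from real
  overlapping data should be fitted with the optional high-side constraint
  and inspected.
* The step-B disjunctive discharge rule can discharge short-but-stable
  cervices; users wanting conservative behaviour should set
  `b_low_rule = "and"`.
* Accuracy sweeps report no confidence intervals; the source analysis
  reported none, and per-row denominators shift with missingness, which any
  interval would need to acknowledge.
* Published cohort-specific cell values (the accuracy-table and
  population-count figures) depend on unavailable clinical data and are
  treated as structural, not numerical, targets throughout.
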