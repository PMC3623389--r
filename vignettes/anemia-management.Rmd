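---
title: "Laboratory-guided preoperative anemia management: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laboratory-guided preoperative anemia management: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preopanemia)
```

## The problem

Preoperative anemia is a major predictor of allogenic red-cell transfusion
in elective orthopedic surgery, and transfusion itself carries risk. A
patient-blood-management program therefore wants to (1) find anemic
patients early, (2) identify the *cause* of the anemia — because iron
deficiency (ID), anemia of chronic disease (ACD) and their combination call
for different doses of intravenous iron and erythropoiesis-stimulating
agent (ESA) — and (3) quantify what the intervention does to hemoglobin
course, transfusion use and cost. This package implements that whole chain
as testable functions: classification, therapy recommendation, eligibility
filtering, cohort accounting, method-agreement statistics and a seeded
synthetic-cohort generator.

## The diagnostic model

The central classifier is the **Thomas plot**, which crosses two markers
that, unlike ferritin and transferrin, are not distorted by acute-phase
reactions:

* the ratio of **soluble transferrin receptor** (sTfR, mg/L) to
  **log10 ferritin** (ferritin in ng/mL) on the x-axis — high values mean
  depleted or unavailable iron stores; and
* **reticulocyte hemoglobin content** (CHr, pg) on the y-axis — values
  below 28 pg mean erythropoiesis is already iron-restricted
  ("functional ID").

The ratio's cut-off depends on the inflammatory state: 1.5 when
CRP ≤ 5 mg/L, 0.8 when CRP > 5 mg/L (ferritin is a positive acute-phase
reactant, so inflammation pushes the ratio down). The four quadrants are
Q1 = ACD without functional ID, Q2 = latent ID, Q3 = manifest ID,
Q4 = functional ID combined with ACD.

```{r thomas}
panels <- lab_panel(hb = c(12.1, 11.4, 12.6), sex = "female",
                    stfr = c(1.1, 3.1, 3.4), ferritin = c(180, 15, 9),
                    crp = c(2, 1, 3), chr = c(30.5, 29.2, 24.8))
classify_thomas(panels)
```

**Tie conventions.** The published definitions use "elevated ratio" and
"CHr < 28 pg", with no equality rule for the ratio cut-off. We assign a
ratio exactly at its cut-off to the ACD side (Q1/Q4) and treat CHr exactly
28 as *not* functional ID. These are documented conventions, not inferred
intent; ties are measure-zero for real analyzer output.

**The log base** of "log ferritin" is taken as base 10, the convention of
the Thomas-plot literature; sources differ and the choice is flagged here
rather than hidden. **Ferritin ≤ 1 ng/mL** makes the logarithm
non-positive; rather than clamping, such panels are routed to manifest ID
with an explicit warning flag, because ferritin that low is itself
unambiguous store depletion.

**Missing values** are never imputed: every derived value carries an
explicit defined/undefined state and the classifiers refuse incomplete
panels.

## The NATA comparator grid

The guideline comparator uses only ferritin and transferrin saturation,
TSAT (%) = serum iron (µg/dL) × 70.9 / transferrin (mg/dL). As printed,
its three "and/or" category definitions overlap; the grid implemented here
is the disambiguation forced by the scheme's two explicitly unclassifiable
cells (ferritin > 100 ng/mL with TSAT < 20%, and ferritin 30–100 ng/mL
with TSAT ≥ 20%). Ferritin < 30 ng/mL dominates regardless of TSAT —
depleted stores define ID in the guideline logic; the ferritin < 30 &
TSAT ≥ 20 cell is our documented decision, not a published claim. The
"30–100" band is closed on both ends. The five cells partition the plane,
which is property-tested on a 10^4-point grid.

## The therapy rule and eligibility filters

Hb ≥ 13 g/dL (men and women alike — the unified therapeutic threshold, a
deliberate departure from the WHO's sex-specific definition) has no
therapeutic consequence. Below it, Q1 receives 200 mg iron i.v. +
40000 I.U. ESA; Q2/Q3/Q4 receive 1000 mg iron i.v. + 10000 I.U. ESA,
scheduled by default 20 days before surgery. The before/after evaluation
excludes records missing a required Hb timepoint (first preoperative Hb
within 90 days, second at 0–3 days before surgery, at least one
postoperative Hb in the first week), records treated within 7 days of
surgery (day −7 inclusive — "within 7 days" is ambiguous and the inclusive
convention is documented), dose deviations from the arm, and cancelled
surgeries; when several apply, the first in that fixed order is reported.

## Cohort accounting

`prevalence()`, `transfusion_summary()`, `reduction_pct()` and
`cost_report()` implement the arithmetic of the cohort tables. Percentages
are rounded half-up (half-even rounding would, e.g., turn 20.5 into 20)
and costs half-up to cents; `units_per_patient` is kept unrounded
internally. The cost model is linear:
units × €135 + iron(mg)/100 × €27.32 + chargeable ESA(I.U.)/1000 × €0.69,
with 40000 I.U. ESA doses free of charge under the hospital agreement the
default `price_table()` encodes. One published per-patient figure (€36.08
for the conventional group) is a truncation of 3645/101 = 36.089…; this
package reports the half-up 36.09 and documents the discrepancy rather
than emulating truncation. Similarly, the "reduced by 60%" figure for
anemic patients is 59.1% under units-per-patient arithmetic; the unrounded
value is reported.

Medians use the mean-of-middle-two convention for even n
(`stats::median()`). Because the source study states no CI method, the Hb
course CIs are seeded bootstrap percentile intervals for medians — a
package design choice.

## Exact tests

The exact nonparametric tests are implemented from first principles, with
brute-force oracles in the test suite:

* **Exact Mann-Whitney U** — U from midranks; the two-sided p enumerates
  all `choose(n1+n2, n1)` group assignments and counts those with
  `|U − n1·n2/2|` at least the observed deviation. Above 14 pooled
  observations a seeded Monte-Carlo permutation p with binomial standard
  error is used (the enumerated path is verified against an independent
  pairwise-count oracle for every split up to pooled n = 10, and against
  the classical exact distribution in the tie-free case).
* **Fisher's exact test** — hypergeometric probabilities from log-binomial
  coefficients; the two-sided p sums probabilities ≤ the observed table's
  (relative tolerance 1e-7, the usual convention).
* **Exact chi-square** (for >2 categories) — the Pearson statistic
  referred to its exact conditional distribution given both margins: full
  enumeration of fixed-margin tables weighted by multivariate
  hypergeometric probabilities when their number is below `enum_limit`,
  otherwise seeded Monte-Carlo over `stats::r2dtable()` draws.
* **Spearman's rho** — Pearson correlation of midranks.

No multiplicity adjustment is applied anywhere; p-values are descriptive,
matching the analysis the pipeline reproduces.

## Method agreement (POCT vs laboratory Hb)

`bland_altman()` uses differences x − y, bias = mean difference, limits of
agreement = bias ± 1.96 × SD (n−1 denominator); 1.96 rather than 2.0 is a
documented choice since the source analysis states neither. Cronbach's
alpha uses the two-item covariance form `2(1 − (var x + var y)/var(x+y))`,
equal to the standardized `2r/(1+r)` form at equal item variances. The
POCT error model in the generator is reference + systematic offset +
per-operator offset + Gaussian noise, reflecting the user-related
variability reported for handheld hemoglobinometers (single values
deviating by more than 2 g/dL).

## The synthetic-cohort generator

Real patient data were never deposited, so the generator *is* the study
bed. Its defaults emulate the published cohort structure: groups of 101
(conventional care) and 234 (algorithm-managed) records; anemic fractions
24/101 and 32/234; anemic etiologies split 40:11:5:0 over
ACD : latent ID : manifest ID : combined functional ID/ACD (the combined
class is reachable but has default weight zero, matching the observed
zero count).

Design choices worth knowing:

* **Region boxes, not Gaussians, for lab values.** Each etiology's labs
  are drawn uniformly inside a box sited in its Thomas-plot region, shrunk
  by a safety margin (default 5% of each span). Gaussian tails would
  straddle the cut-offs and make the generating label ambiguous; with a
  positive margin, classifier agreement with the generating etiology is
  exactly 100%, which the acceptance properties rely on.
* **Hb courses.** Hb1 is a per-etiology truncated normal (anemic records
  truncated below 13 g/dL, non-anemic above — means/SDs are plausible
  configuration, since the source reports medians and ranges but no
  dispersions). Hb2 adds a small preoperative drift (mean −0.2 g/dL) plus,
  for treated records, a therapy effect of mean +0.75 g/dL (SD 0.35) —
  together reproducing the reported anemic-group medians (12.45 → 13.0
  treated vs 12.15 → 11.95 untreated). Hb3/Hb4 subtract an operative drop
  (mean 2.5) and a later postoperative change (mean 0.75).
* **Transfusion.** The source hospital used no strict transfusion rule, so
  nothing printable can be copied: transfusion is Bernoulli with a
  decreasing step probability in Hb2 (0.50/0.30/0.18/0.08/0.05 below/above
  10, 11, 12, 13 g/dL) and 1–3 units per transfused patient, calibrated
  once to land near the reported ~8%/~6% group rates.
* **Determinism.** A single integer seed in the design governs all draws,
  scoped so the caller's RNG state is untouched; the same design and seed
  are byte-identical.

What the generator does *not* emulate: longitudinal erythropoiesis
dynamics, correlation between comorbidity and etiology, device-specific
POCT failure modes, and measurement rounding. Passing tests on synthetic
cohorts therefore demonstrate correctness of the *pipeline* under the
stated statistical structure — not clinical validity on real data.

## Configuration

Every threshold (13/12 g/dL, 28 pg, 1.5/0.8, CRP 5, NATA 30/100/20%, the
price table, the 7-day window, the 20-day scheduling default) lives in
`pbm_config()`; functions take the config as an argument, so one override
propagates consistently and is visible in call signatures rather than
buried as literals.

```{r pipeline}
coh <- generate_cohort(cohort_design(seed = 20131))
report <- run_pipeline(coh, paired = paired_poct(coh[coh$group == "II", ],
                                                 seed = 20131))
report
```

## Problem sizes and numerical notes

The test suite enumerates Mann-Whitney assignments up to pooled n = 10
against its oracle (the implementation enumerates up to 14 by default),
checks Fisher against the factorial oracle exhaustively to N = 16 plus
seeded larger tables to N = 30, uses 10^4-point partition grids, 100
Bland-Altman replicates at the study's pairing size n = 233, and an
etiology-mix check at 56 × 100 records — sizes chosen to make binomial and
Monte-Carlo tolerances tight while the whole suite stays fast. Floating
point: rank-deviation comparisons use a 1e-9 slack; probability-tie
comparisons in Fisher use the standard 1e-7 relative tolerance; rounding
to printed precision is half-up, applied only at the reporting boundary.

## Known limitations

The eligibility filter reports one (the first) violated criterion per
record; the NATA grid is only the ferritin/TSAT fragment used for the
comparison, not the full guideline; Bland-Altman here has no
regression-based alternative (Passing–Bablok, Deming are out of scope);
and the cost model covers product purchase prices only — no laboratory or
staff costs.
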