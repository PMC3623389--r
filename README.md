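# preopanemia

Laboratory-guided classification and management of preoperative anemia.

Anemic patients facing elective orthopedic surgery are far more likely to
receive allogenic red-cell transfusions, and transfusion itself carries
risk. Patient-blood-management programs therefore screen hemoglobin weeks
before surgery, diagnose the *cause* of any anemia, and substitute iron
and/or erythropoiesis-stimulating agent (ESA) accordingly. This package
implements that pipeline for analysts evaluating such programs: the
diagnostic classifiers, the therapy decision rule, the study eligibility
filters, cohort-level transfusion/cost accounting, exact nonparametric
tests, method-agreement statistics for point-of-care vs laboratory
hemoglobin, and a seeded synthetic-cohort generator so everything runs and
is testable without patient data.

## The model at its core

The diagnostic engine is the **Thomas plot**. For a panel with soluble
transferrin receptor sTfR (mg/L), ferritin (ng/mL), CRP (mg/L) and
reticulocyte hemoglobin content CHr (pg):

- index: `r = sTfR / log10(ferritin)`
- cut-off: `c = 1.5` if CRP ≤ 5 mg/L, `c = 0.8` if CRP > 5 mg/L
- functional iron deficiency: `CHr < 28 pg`

| | `r ≤ c` | `r > c` |
|---|---|---|
| **CHr ≥ 28** | Q1: ACD | Q2: latent ID |
| **CHr < 28** | Q4: functional ID + ACD | Q3: manifest ID |

Therapy (applied when Hb < 13 g/dL, men and women alike): Q1 → 200 mg iron
i.v. + 40000 I.U. ESA; Q2/Q3/Q4 → 1000 mg iron i.v. + 10000 I.U. ESA. The
comparator grid (NATA guideline) classifies on ferritin bands 30/100 ng/mL
and transferrin saturation `TSAT (%) = iron (µg/dL) × 70.9 / transferrin
(mg/dL)` at 20%, and leaves two of its five cells unclassifiable.

## Worked example

```r
library(preopanemia)

# classify one anemic panel
classify_thomas(lab_panel(hb = 11.4, sex = "female", stfr = 3.1,
                          ferritin = 15, crp = 1, chr = 24.8))
#>     ratio ratio_cutoff  chr functional_id ratio_undefined       quadrant
#> 1 2.63585          1.5 24.8          TRUE           FALSE Q3_MANIFEST_ID
```

The index 3.1/log10(15) = 2.64 exceeds the low-CRP cut-off 1.5 and CHr is
below 28 pg: manifest iron-deficient erythropoiesis (Q3), so the
recommendation would be the high-dose iron arm (1000 mg + 10000 I.U.).

```r
# a full synthetic before/after cohort through the whole pipeline
coh <- generate_cohort(cohort_design(seed = 20131))
report <- run_pipeline(coh, paired = paired_poct(coh[coh$group == "II", ],
                                                 seed = 20131))
report
#> Preoperative anemia management report
#>   reviewed 335, included 335, excluded 0
#>   prevalence: unified 18.2%, WHO 10.4%
#>   Thomas quadrants: Q1_ACD=43, Q2_LATENT_ID=12, Q3_MANIFEST_ID=6, Q4_FUNCTIONAL_ID_ACD=0
#>   therapy arms: NONE=0, ACD_ARM=43, ID_ARM=18
#>   group I: 3/101 transfused (3%), 7 RBC units, cost 945.00 EUR
#>   group II: 11/234 transfused (5%), 13 RBC units, cost 6372.92 EUR
#>   units/patient reduction (I -> II): 20%
#>   POCT agreement: bias -0.23, LoA [-1.23, +0.77], r 0.905, alpha 0.948
```

Reading this: 335 simulated records pass the eligibility filters; under
the unified 13 g/dL threshold 18.2% are anemic (10.4% under the WHO
definition); the anemic, lab-complete records split across the Thomas
quadrants and map to therapy arms; each group's transfusion count, RBC
units and product cost follow; and the paired point-of-care measurements
show a −0.23 g/dL bias with 95% limits of agreement of about ±1 g/dL.
`write_report(report, "out/")` saves the full bundle as JSON plus a text
summary. Cohorts round-trip through CSV with `write_cohort()` /
`read_cohort()`, and a thin command-line wrapper lives at
`inst/cli/preopanemia.R` (`simulate`, `classify`, `run`).

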