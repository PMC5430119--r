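# gfrpc — GFR from plasma clearance of exogenous markers

`gfrpc` estimates glomerular filtration rate (GFR) from the plasma
disappearance curve of an IV-bolus filtration marker (iohexol,
FITC-inulin), for researchers running longitudinal kidney-function studies
in rodents who need something more sensitive than plasma creatinine or
urea and more practical than urinary inulin clearance.

After a single injection of dose *D*, plasma clearance is

    PC = D / AUC,     AUC = ∫ C(t) dt

and the package provides four estimators of the AUC from timed plasma
samples:

| method | model | clearance |
|---|---|---|
| `clearance_trapezoidal` | model-free trapezoids + log-linear tail to a residual threshold | `D / (AUC_obs + AUC_tail)` |
| `fit_two_compartment` | `C(t) = A e^(−αt) + B e^(−βt)` (NLS, curve-stripping start) | `D / (A/α + B/β)` |
| `fit_one_compartment` | `C(t) = B e^(−βt)` from 30 min onward (log-linear OLS) | `D β / B` |
| `clearance_two_sample` | monoexponential through two timed samples | `D β / B`, identical to a two-point one-compartment fit |

Around the estimators sit the method-agreement statistics used to compare
them (signed bias and its SD, percent bias, P10/P15 accuracy,
1/C²-weighted regression R², Bland–Altman limits at bias ± 2 SD), a
repeated-measures screen for the first week a measure departs from
baseline, a line-versus-sixth-order-polynomial F-test for the shape of the
biomarker/GFR relationship, an evaluator ranking two-sample schedule
permutations against full-curve references, and a synthetic longitudinal
rat cohort with known ground-truth clearance (8 animals × 6 weeks on the
12-point schedule 0–300 min, biexponential markers, LLOQ censoring,
hyperbolic endogenous markers) against which every stage is validated.

## Worked example

Simulate a declining cohort, estimate clearance by all four methods, and
summarize method agreement:

```r
library(gfrpc)

co  <- simulate_cohort(seed = 1)
est <- estimate_clearances(co$sessions)
head(est[est$method == "trapezoidal",
         c("subject_id", "week", "marker", "clearance_ml_min")])
#>    subject_id week  marker clearance_ml_min
#> 1          A1    0 iohexol            2.536
#> 5          A1    0  inulin            2.510
#> 9          A1    1 iohexol            1.777
#> 13         A1    1  inulin            1.759
#> 17         A1    2 iohexol            1.324
#> 21         A1    2  inulin            1.355
```

Week-0 clearances sit near the healthy 2.5 mL/min baseline and fall with
the induced decline. The agreement table (one row per reference/
comparative pair, 48 animal-weeks each) shows the structural story:

```r
cmp <- compare_methods(est)
cmp[c(2, 5, 11), c("reference", "comparative", "n", "r2",
                   "bias", "precision", "pct_bias", "p10")]
#>             reference             comparative  n   r2    bias precision pct_bias p10
#> 2  inulin_trapezoidal     iohexol_trapezoidal 48 1.00 -0.0075     0.040   -0.325 100
#> 5  inulin_trapezoidal  inulin_one_compartment 48 0.99 -0.3122     0.337  -14.794  40
#> 11 iohexol_trapezoidal iohexol_one_compartment 48 0.99  0.0036     0.076    0.356  96
```

The two markers agree almost perfectly under full-curve estimation (row
2: bias −0.008 mL/min, every pair within 10%). Collapsing the
slow-equilibrating inulin-like marker to one compartment biases clearance
high — a −14.8% signed bias against the trapezoidal reference and only
40% of pairs within 10% (row 5) — because its distribution phase carries
~31% of the AUC. The fast-equilibrating iohexol-like marker survives the
same simplification essentially unbiased (row 11), which is what makes a
routine two-sample iohexol protocol possible; `evaluate_schedules()`
ranks the candidate `(t1, t2)` pairs and finds (30, 90) min the most
accurate.

`vignettes/plasma-clearance-methods.Rmd` documents the models, the
conventions behind every statistic, the generator's parameters, and the
package's numerical choices.

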