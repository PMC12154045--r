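# periostage

Cascaded logistic staging of periodontitis from non-clinical inputs.

Periodontitis affects roughly half of dentate adults, but staging it
(health vs stage I, II or III) normally requires a clinical examination.
`periostage` implements a purely statistical screening cascade that
estimates the stage from inputs a layperson can supply: an aMMP-8
mouth-rinse point-of-care test dichotomized at 20 ng/mL, the Visible
Plaque Index (VPI), the number of teeth present, smoking/diabetes status,
annual dental attendance, age and simple anthropometry.

## The model

Three fixed logistic scoring functions, each
`p = 1 / (1 + exp(-(β0 + β·x)))` on risk-coded composite features, chained
as a decision tree:

1. **Severe-disease screen** (cut-off 0.598) on four binary composites
   (aMMP-8+ or diabetic; age × waist-to-height ratio ≥ 26; not (VPI < 50%
   and annual visits); not (full dentition and non-smoker)). Scores
   ≥ 0.598 go to step 3, others to step 2.
2. **Detection function** (cut-off 0.55) on (aMMP-8+ or smoker;
   age × waist circumference; patient or parent diabetic) → *healthy* vs
   *stage I*.
3. **Stage II/III split** (cut-off 0.326) on (aMMP-8+ or > 6 missing
   teeth; VPI ≥ 70% or smoker or diabetic) → *stage II* vs *stage III*.

Around the cascade the package provides the full apparatus used to develop
and evaluate such models: cohort CSV I/O with validation, a
diagnostic-test evaluation toolkit (sensitivity/specificity/F1/phi,
Youden-optimal cut-offs, ROC/AUC, Wald confidence intervals,
Hosmer–Lemeshow calibration), a logistic model-development framework
(maximum-likelihood fitting, Wald inference, backward stepwise selection,
VIF/Cook's distance/EPV diagnostics), and a seed-reproducible synthetic
cohort generator emulating the development study's stage-wise covariate
structure. See `vignette("periostage-methods")` for the science and the
design decisions.

## Worked example

```r
library(periostage)

cohort <- generate_cohort(n = 6, seed = 1)   # synthetic patients
classify_cohort(cohort)[, c("id", "s1", "srisk", "s23", "predicted_stage")]
#>        id     s1  srisk     s23 predicted_stage
#> 1 SYN0001 0.8580     NA 0.15213              II
#> 2 SYN0002 0.1871 0.3189      NA         healthy
#> 3 SYN0003 0.8580     NA 0.02399              II
#> 4 SYN0004 0.5364 0.9995      NA               I
#> 5 SYN0005 0.8580     NA 0.12057              II
#> 6 SYN0006 0.5364 0.9056      NA               I
```

`s1` is the severe-disease screen's probability; each record then carries
exactly one of `srisk` (healthy/stage I branch) or `s23` (stage II/III
branch). Patient 2, for instance, scores 0.187 < 0.598 on the screen and
0.319 < 0.55 on the detection function, so is called healthy; patients 1,
3 and 5 cross 0.598 but stay below 0.326 on the split, so are called
stage II.

Evaluation against known stages:

```r
res <- classify_cohort(generate_cohort(n = 149, seed = 1))
staging_report(res, generate_cohort(n = 149, seed = 1)$true_stage)
#> <staging_report>
#> -- periodontitis detection --
#> <metric_report> positive = I|II|III  n = 149
#>   sensitivity 0.983 (0.959-1.007)  specificity 0.441 (0.274-0.608)
#>   ...
#> -- staging among detected: 62/113 = 0.549 (0.457-0.640) --
```

A command-line pipeline wraps the same functions
(`exec/periostage simulate|score|evaluate|refit|report`), e.g.

```sh
exec/periostage simulate --n 149 --seed 1 --out cohort.csv
exec/periostage score --in cohort.csv --out pred.csv
exec/periostage evaluate --pred pred.csv --truth cohort.csv --out report.json
```

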