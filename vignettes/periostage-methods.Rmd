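---
title: "Staging periodontitis with a cascaded logistic model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging periodontitis with a cascaded logistic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periostage)
```

## The problem and the model

Periodontitis staging (health, stage I, II, III under the 2018
classification) normally requires clinical attachment-loss or radiographic
measurements. This package implements a purely statistical screening
alternative built from inputs a layperson can supply: an aMMP-8
(active matrix metalloproteinase-8) mouth-rinse point-of-care test
dichotomized at 20 ng/mL, the Visible Plaque Index (VPI, the percentage of
tooth surfaces with visible plaque), the number of teeth present (third
molars excluded), smoking and diabetes status, annual dental attendance,
age and simple anthropometry.

The model is a cascade of three logistic scoring functions, each of the form

$$p = \frac{1}{1 + e^{-(\beta_0 + \beta_1 x_1 + \dots + \beta_k x_k)}},$$

with risk-coded composite features, fixed published coefficients and fixed
operating cut-offs:

1. **Severe-disease screen** (`periostage1`, cut-off 0.598): separates
   health/stage I from stage II/III using four binary composites —
   aMMP-8-positive or diabetic; age × waist-to-height ratio ≥ 26
   (two-decimal comparison); not (VPI < 50% and annual dental visits); not
   (full 28-tooth dentition and non-smoker).
2. **Detection function** (`periorisk`, cut-off 0.55), applied on the mild
   branch: aMMP-8-positive or smoker; age × waist circumference
   (years·cm, advisory input window 2200–8772); patient or parent diabetic.
   Scores ≥ 0.55 mean periodontitis, i.e. stage I on this branch.
3. **Stage II/III split** (`periostage23`, cut-off 0.326): aMMP-8-positive
   or more than 6 missing teeth; VPI ≥ 70% or smoker or diabetic. Scores
   ≥ 0.326 mean stage III.

All slopes are positive on risk-coded features, so each score is strictly
increasing in every risk factor; the cut-offs are applied to full-precision
scores (no rounding, no clipping), and the branch taken is determined solely
by the first score against 0.598.

```{r cascade-example}
fns <- periostage_functions()
logistic_score(fns$periostage23, c(1, 1)) # the closed-form fixture 0.50025
cohort <- generate_cohort(n = 6, seed = 1)
classify_cohort(cohort)[, c("id", "s1", "srisk", "s23", "predicted_stage")]
```

### Numerical conventions

* The published comparison rules are stated "with two decimal places"
  (25.99 < 26; 49.99 < 50; 69.99 < 70). We round **half-up** to 2 dp and
  then compare exactly as written; the published examples pin only the
  comparison direction, and half-up is the conventional reading. VPI is
  ingested at the same precision.
* The exponent is the negated full linear predictor (the standard logistic
  form); this choice reproduces the published odds ratios
  (`Exp(B) = e^B > 1` for all slopes) and makes every score increasing in
  risk.
* Two of the functions are verbally described as probabilities of the
  *negative* condition while their decision rules treat high scores as
  positive; the decision rules are taken as authoritative and scores are
  documented as probabilities of the positive (more severe) branch.
* Waist-to-height ratio is cm/cm (≈ 0.55–0.65 in adults). The published
  "ratio window 13.50–56.42" is dimensionally consistent only with the
  *product* age × ratio (25 × 0.54 = 13.5, 78 × 0.72 ≈ 56.2), and is
  treated as that product's advisory window, not asserted as authorial
  intent.
* Out-of-window inputs (age outside 25–78, waist outside 60–152 cm, height
  outside 150–193 cm, PERIORISK's x2 outside 2200–8772) are **scored with a
  warning** by default: the windows describe where the functions were
  developed, not data validity. `strict = TRUE` escalates them to errors.

## Evaluation statistics

`basic_rates()`, `phi_coefficient()`, `chi_square_2x2()`, `wald_ci()`,
`roc_and_auc()`, `youden_optimal_cutoff()`, `hosmer_lemeshow()` and
`staging_report()` implement the evaluation toolkit. Conventions worth
recording:

* **Confidence intervals** are normal-approximation (Wald) intervals with
  `z` fixed at 1.96 at the 95% level — this convention reproduces all six
  published intervals of the complete model to their printed decimal. They
  are deliberately not clipped to [0, 1]; Wilson/score intervals are out of
  scope.
* **Chi-square** is the uncorrected Pearson independence statistic, so the
  identity `phi^2 * n = chi2` holds exactly. The development study also
  quotes two goodness-of-fit chi-squares on 1 df that are not reproducible
  from its printed 2×2 tables (which give 39.63 and 17.70); both this test
  and the Hosmer–Lemeshow calibration test are provided, and neither claims
  to reproduce those printed values.
* **ROC/AUC**: thresholds sweep the unique observed scores with the rule
  "positive at score ≥ threshold"; trapezoid area equals the normalized
  Mann–Whitney U with ties counted 1/2 (a tested invariant). Scores are
  oriented "higher = more diseased"; AUC < 0.5 warns rather than
  auto-flips.
* **Youden-optimal cut-offs** break ties toward the higher (more specific)
  threshold.
* Rates with zero denominators are reported absent (`NA`), never as 0.
* **Staging accuracy** is computed among true periodontitis cases that the
  cascade also detected as periodontitis, overall and per true stage —
  the reporting structure used for the complete model.

## Model development framework

`fit_logistic()` maximizes the Bernoulli likelihood by Newton/IRLS with
step-halving (the log-likelihood never decreases), converging on the score
max-norm at 1e-8 with a 100-iteration cap; standard errors come from the
inverse observed information. Diverging coefficients (|B| > 15) are the
signature of perfect separation; such fits are flagged and reported, never
silently returned (no penalized fallback is applied). The tests verify the
optimizer against a brute-force likelihood grid on tiny instances and
against an independent IRLS implementation on larger ones.

`backward_stepwise()` removes, at each step, the predictor with the largest
Wald p-value above the threshold (0.05 in the development protocol),
matching the "backward: Wald" selection family whose statistics the
published coefficient table reports; likelihood-ratio removal is not
implemented. The intercept is never removed.

`model_diagnostics()` provides VIF (`1/(1 - R^2)` via auxiliary linear
regressions), standardized Pearson residuals, the standard GLM
generalization of Cook's distance on the weighted working response
(flagging Cook's > 0.5 or |residual| > 3.0), and a Durbin–Watson statistic
on residuals in record order — the quantitative counterpart of a visual
residual-versus-time check, record order standing in for time.
`epv_check()` applies the events-per-variable admissibility rule: events =
the smaller outcome-class count, admissible when events/terms ≥ 10.

## The synthetic cohort generator

No patient-level data are public, so `generate_cohort()` emulates the
development cohort's published stage-wise structure: stage priors
proportional to 31/14/81/23; per-stage Bernoulli prevalences for gender,
smoking, diabetes, annual dental visits and aMMP-8 positivity taken as the
published count ratios; and per-stage truncated-normal continuous
covariates at the published mean ± SD, truncated to the scoring windows
(age 25–78, waist 60–152 cm, height 150–193 cm, VPI 0–100). Choices the
published tables do not determine, made once:

* **Conditional independence given stage** is the central simplifying
  assumption — only marginals are published. Real covariates are
  correlated (age with tooth loss, smoking with plaque), so synthetic
  cohorts will generally show *different* joint behaviour; passing tests
  demonstrate correctness of the machinery and parameter recovery, not
  clinical performance on real patients.
* Tooth count is truncated to [12, 28] (integers) rather than the study's
  ≥ 20-teeth inclusion criterion, so the "> 6 missing teeth" feature is
  exercised; callers wanting the inclusion rule filter afterwards.
* Weight is truncated to [45, 160] kg, a physiologic range consistent with
  the published means ± SD (no window is published for weight).
* Parental diabetes is not characterized in the published tables; it is
  drawn at a configurable default prevalence of 0.15 (regional adult
  diabetes prevalence of roughly 10% plus an undiagnosed margin),
  explicitly a placeholder.
* aMMP-8 is generated as the positivity flag (only the dichotomy is
  published); `fill_concentration = TRUE` back-fills concentrations from
  two log-normals straddling 20 ng/mL for interface testing only.
* Serialization precisions for the CSV round-trip contract: VPI 2 dp,
  waist/height/weight 1 dp, concentration 2 dp, age and tooth counts
  integer, booleans 0/1.

The generator is bit-reproducible under a seed, and
`parameter_recovery_experiment()` closes the loop: cohorts are generated,
outcomes simulated from a shipped scoring function, and the coefficients
refit. At n = 5000 with 200 replicates the stage II/III coefficients are
recovered with |mean bias| < 0.05 and ~95% Wald-interval coverage
(problem sizes chosen so the whole study runs in seconds on one CPU; the
same harness scales up unchanged).

```{r recovery, eval = FALSE}
rec <- parameter_recovery_experiment(periostage_functions()$periostage23,
                                     n = 5000, replicates = 200, seed = 1)
rec$summary
```

## Known limitations

* The cascade's coefficients and cut-offs are population-specific fixtures
  from one 149-patient development cohort, tested on the data that formed
  it; nothing here constitutes external validation.
* The synthetic generator cannot reproduce the development cohort's joint
  covariate distribution, its AUCs or its confusion counts, and does not
  attempt to.
* Grade (A/B/C) is not predicted — no grading function is published — and
  clinical staging from attachment loss is consumed as a label, never
  computed.
* Wald intervals misbehave near proportions of 0 or 1 (zero width at
  p = 1); they are kept because they are the development study's
  convention.
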