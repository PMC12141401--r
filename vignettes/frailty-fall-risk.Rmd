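---
title: "Methods: laboratory frailty and in-hospital fall risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laboratory frailty and in-hospital fall risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtyfalls)
```

`frailtyfalls` implements an end-to-end pipeline for one question: whether a
laboratory-based deficit-accumulation frailty index (FI-lab) adds predictive
value for in-hospital falls beyond a conventional admission screening score
(STRATIFY). This vignette is the package's account of the underlying methods:
the scores and their eligibility rules, the model suite, the incremental-value
and validation machinery, the synthetic-data generator the tests run against,
and the numerical and design choices that were genuinely open.

## Deficit-accumulation scores

The deficit-accumulation view of frailty counts health deficits as a fraction
of deficits assessed. FI-lab applies this to a panel of routine laboratory
tests: each analyte contributes 1 if its value lies outside the reference
interval, 0 otherwise, and the index is the abnormal count divided by the
number of tests actually performed. Three conventions matter and are fixed
here:

* **Boundary values are normal.** A sodium of exactly 135 mmol/L with
  interval [135, 145] scores 0. The literature rarely states this; we chose
  the inclusive interval and apply it uniformly (`flag_abnormal()`).
* **Eligibility is an exact rational comparison.** FI-lab is computed only
  when at least 70% of the panel was measured; with the default 35-analyte
  panel, 25/35 passes and 24/35 fails. The comparison is `measured * 10 >=
  panel_size * 7` in integer arithmetic, never a rounded percentage.
* **First result wins.** When an analyte is measured more than once around
  admission, the earliest result is used; ties on the recorded sequence
  number fall back to file order. Deduplication happens at cohort
  construction, which is why downstream scoring is invariant to row order.

The shipped panel (35 analytes, complete blood count plus standard chemistry,
sex-specific intervals where conventional) is configuration, not code: the
exact analyte list and cut-offs vary by laboratory, so
`inst/extdata/panel_default.yaml` uses textbook adult intervals and is meant
to be replaced by each site's own. The same holds for the 40-item clinical
frailty index schema (`fi_clinical_items.yaml`): its domains — symptoms and
signs, BMI, comorbidities, functional ability, cognition, sensory function —
follow the standard construction, with generic item identities. FI-clinical
values are 0 / 0.5 / 1 per item, the index is the deficit sum over items
assessed, and at least 80% of the 40 items must be assessed (32/40 passes,
31/40 fails, again exact).

STRATIFY is the sum of five binary items; the mental-status item follows the
modified criterion covering confusion, disorientation and agitation rather
than agitation alone. The six-item extension adds one point when FI-lab
exceeds 0.4 — a score of exactly 0.4 does not earn the point, matching the
"≤ 0.4 versus > 0.4" dichotomy used for the binary FI-lab variable. Bands
use the conventional cut-offs (< 0.25, 0.25–0.4, > 0.4), so band "high" and
binary 1 coincide by construction.

The Charlson Comorbidity Index uses the Quan ICD-10 prefix coding with the
original Charlson weights (`cci_icd10_quan.csv`); which mapping a given study
used is often unstated, so the mapping is a swappable data file. Hierarchical
pairs (diabetes with/without complication, mild versus moderate/severe liver
disease, malignancy versus metastasis) count once at the higher weight.

## Exclusions

Two rules, applied before any scoring: readmissions within 30 days of a
previous discharge are removed (`readmission_gap_days <= 30`, measured in
whole days; the boundary day 30 is excluded, day 31 retained — the
"within 30 days" phrase does not resolve the boundary, so we fixed it on the
inclusive side), and admissions with fewer than 70% of panel analytes
measured are removed as FI-lab-ineligible. `apply_exclusions()` reports the
two-way tally (readmission-only, labs-only, both, included), which always
sums to the raw count.

## The model suite

All models are maximum-likelihood logistic regressions of the fall indicator,
fitted by iteratively reweighted least squares (`stats::glm`, deviance
tolerance 1e-10) and always containing age (years, untransformed) and sex.
Sex is coded male = 1 against a female reference; the direction is a
convention, documented in the output. The suite:

| id | predictors beyond age + sex |
|----|------------------------------|
| m1 | STRATIFY |
| m2 | STRATIFY + FI-lab |
| m3 | six-item STRATIFY-including-FI-lab |
| m4 | STRATIFY + FI-clinical |
| m5 | FI-lab + FI-clinical |
| m6 | STRATIFY + FI-lab + FI-clinical |

Confidence intervals are Wald (`exp(unit · (β ± 1.959964 SE))`) — the
standard reporting style for this kind of table; profile-likelihood intervals
were deliberately not used. Frailty indices are reported per 0.1 unit,
STRATIFY per point. The events-per-variable ratio for the primary model
(events / 4) is reported as a stability guardrail. Perfect separation is
detected from exploding coefficients or standard errors and flagged rather
than silently returned; single-sex subgroups keep the (then aliased) sex term
estimable by using a numeric male indicator. Sensitivity analyses append the
polypharmacy score and/or CCI as covariates. Subgroup suites stratify at age
75 (75 itself joins the older stratum) or by sex; strata with a single
outcome class are skipped with a warning.

## Incremental value

The AUROC is computed as the Mann–Whitney pair statistic with half credit for
ties, via midranks; the trapezoidal integral of the ROC curve equals it to
machine precision and both are retained as a cross-check. Paired AUROC
comparison follows DeLong's structural-components construction: placement
values per subject, a 2×2 covariance, a two-sided normal test (no
small-sample correction). When the variance of the difference is numerically
zero — identical or rank-identical scores — the comparison is flagged
degenerate and reported as delta 0, p 1.

The NRI is the **category-free (continuous)** version: net proportion of
events whose predicted risk rises plus net proportion of non-events whose
risk falls, range −2 to 2. Exact ties in predicted risk count for neither
direction (the source literature is silent on ties; this is the conservative
choice). Inference uses the asymptotic variance of the two net proportions,
with a subject-resampling bootstrap CI as an option since the reporting
convention differs across studies. The IDI is the change in the mean-risk
gap between events and non-events, with a paired-difference standard error.
Reclassification against a reference score that the new model dropped is not
meaningful, so NRI/IDI cells are reported `NA` for such comparisons (the
FI-lab + FI-clinical model against the STRATIFY reference); the six-item
score counts as containing STRATIFY.

The "best" binary cutpoint for a score maximizes the Youden index J =
sensitivity + specificity − 1 over midpoints between consecutive distinct
observed values, plus the two degenerate boundary thresholds (J = 0), with
ties broken toward the lower cutpoint. Youden's J is assumed because the
criterion behind published "optimal" cutpoints is usually unstated.

## Internal validation

`validate_model()` implements the enhanced (Efron/Harrell) bootstrap with
admission-level resampling: for each of B resamples the model is refitted,
the c-statistic optimism is the mean of (c on the resample − c of that refit
on the original data), and the corrected c is the apparent c minus the mean
optimism. The calibration slope is the mean over resamples of the coefficient
from regressing the original outcomes on the resample model's linear
predictor — averaged over resamples, not refit once. Calibration error is
summarized against the optimism-corrected calibration curve: the apparent
lowess curve of outcome on predicted probability (span 2/3, no robustness
iterations — robust reweighting misbehaves on 0/1 outcomes), shifted by the
mean bootstrap optimism of that curve, evaluated at each admission's
prediction; we report the mean and the 0.9 quantile (type-7) of the absolute
errors. Non-converged or separated resamples are skipped and counted; more
than 5% skipped flags the report unstable, and B < 50 warns. The seed is
mandatory and recorded, so a report is reproducible byte for byte.

## The synthetic-cohort generator

`sim_config()` / `simulate_cohort()` generate admission records with the
marginal structure of a geriatric acute-care cohort, which is what the tests
and the acceptance script run against. Defaults, chosen once to emulate the
study conditions: age truncated-normal mean 73 SD 7.3 on [60, 99] (truncation
pulls the realized mean about half a year above 73), 63.5% male, 25.9%
emergency admissions, per-analyte abnormality probability 0.31 (so mean
FI-lab ≈ 0.31), per-analyte missingness 0.13 (mean measured ratio ≈ 0.87,
and a small tail of FI-lab-ineligible admissions), STRATIFY item prevalences
13.5 / 5.9 / 7.4 / 7.0 / 8.4%, clinical deficit rates giving mean
FI-clinical ≈ 0.11 with 5% item missingness, and a logistic fall model with
coefficients on the reported odds-ratio scales (per 0.1 unit for the frailty
indices) and a marginal event rate calibrated to 2.9%.

Design choices worth stating:

* **Out-of-range magnitude is irrelevant.** Abnormal laboratory values are
  drawn uniformly on a band of width half the reference interval beyond the
  violated limit; FI-lab only sees the binary deviation, so only the side and
  probability matter.
* **Intercept calibration.** When a target marginal rate is set, the
  intercept is solved by bisection so that the *expected* rate
  `mean(plogis(c + η))` over the realized covariates matches the target
  (within 1e-4; the solver tolerance is tighter). A target outside (0, 1) is
  a configuration error.
* **Independence by default.** Deficits and abnormalities are independent
  across items given the config. An optional latent frailty factor
  (logistic-normal shift shared across all of a patient's deficit
  probabilities) can induce correlation, but the default is off: observed
  FI-lab correlations with other scores are weak (r ≤ 0.37 in the motivating
  data), and independence is the honest default rather than a tuned
  correlation structure. A consequence is that the default cohort's FI-lab
  SD (~0.08, binomial) is smaller than the ~0.16 seen in real cohorts, and
  model AUROCs in the emulation (~0.60–0.65) sit below published values —
  the synthetic conditions exercise the *machinery*, they do not reproduce a
  real cohort's joint distribution, and passing tests should be read
  accordingly.
* **RNG.** One R RNG stream seeded once from the config, with a fixed draw
  order, gives full reproducibility from (config, seed). Per-record
  counter-based substreams would additionally make records order-independent;
  that refinement was dropped as R provides no counter-based generator and
  determinism of the whole table is what the pipeline needs.
* `simulate_scores()` is a score-level fast path through the same generating
  process (fully measured panel, no long tables) for large Monte-Carlo work:
  population-AUROC estimation (`true_auc()`, default 10^6 draws),
  parameter-recovery and test-size simulations.

## Problem sizes in the checks

The test suite exercises the statistical properties at sizes chosen to make
Monte-Carlo noise negligible relative to the assertion: exclusion-flow and
score arithmetic on a constructed 7661-admission cohort; AUC oracle
equivalence on 10,000 enumerable instances (n ≤ 12); DeLong test size over
2,000 replicates of n = 1,000 under an exchangeable-scores null (two noisy
copies of one informative predictor at event rate 0.3 — adding pure noise to
a score would *lower* its population AUC, so the exchangeable construction is
the correct equal-AUC null); coefficient recovery and pooled CI coverage over
200 replicates at n = 50,000; calibration-slope behaviour at n = 20,000 with
B = 200, and overfitting detection with 40 noise predictors at n = 400 over
100 replicates. `scripts/acceptance.R` re-runs the study emulation at
n = 5,984 with B = 200 validation resamples.

## Known limitations

* The default panel and deficit schema are generic stand-ins for
  site-specific configuration; results on them are structurally, not
  clinically, meaningful.
* No multiple imputation: analyses are complete-case by design, with
  eligibility rules standing in for missing-data handling, as in the
  motivating analysis.
* One row per admission after exclusions — no clustering of repeat patients,
  no time-to-event structure, no competing risks.
* The NRI/IDI inference is asymptotic by default; for small event counts the
  bootstrap option is preferable.
* DeLong comparisons of *nested models refit on the same training data* are
  known to be conservative; the package reports them because that is the
  field's convention, but the size guarantee in the tests is established
  under the exchangeable-scores null, not the nested-refit setting.
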