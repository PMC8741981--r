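---
title: "Mechanical-power indices for weaning readiness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical-power indices for weaning readiness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weanpower)
```

## The clinical problem

Prolonged mechanically ventilated, tracheotomized patients are periodically
tested for readiness to breathe on their own with a spontaneous breathing
trial (SBT): the patient is disconnected from the ventilator and breathes
unassisted through a T-piece for 30 minutes while vital signs and an
end-of-trial arterial blood gas are monitored. A failed trial is one where
objective respiratory distress appears (breathing frequency > 35/min,
heart rate > 130 bpm, systolic blood pressure > 160 mmHg, SpO2 < 88 %) or
the blood gas shows ventilatory failure (PaCO2 > 45 mmHg). `weanpower`
implements a family of ventilator-derived indices intended to predict that
outcome *before* the trial, from a one-time readout of the ventilator
display and a simultaneous blood gas — no disconnection, no esophageal
manometry — together with the full statistical machinery needed to evaluate
any such index: ROC analysis, a cross-validated diagnostic metric battery,
and logistic regression modeling.

## The indices

All quantities derive from six primitives measured under pressure-controlled
ventilation: tidal volume $V_T$ (mL), respiratory rate $RR$, minute
ventilation $MV$ (L/min), PEEP and peak inspiratory pressure $P_{max}$
(cmH2O), and PaCO2 on the ventilator (mmHg), plus gender and height.

* **Dynamic driving pressure** $\Delta P_{aw} = P_{max} - \mathrm{PEEP}$.
* **Dynamic lung–thorax compliance** $LTC_{dyn} = V_T / \Delta P_{aw}$
  (mL/cmH2O).
* **Mechanical power**, the energy delivered per minute, in the simplified
  pressure-controlled form
  $MP = 0.098 \cdot RR \cdot V_T[\mathrm{L}] \cdot P_{max}$ (J/min). The
  constant converts cmH2O·L to joules; we fix it at 0.098 exactly (not
  0.0980665) so the normalization below cancels it without residue.
* **PBW-MP**: $MP$ per kg of predicted body weight, where PBW uses the
  standard height/gender formula ($50$ or $45.5 + 0.91(h - 152.4)$ kg), a
  surrogate of healthy lung size.
* **LTC$_{dyn}$-MP**: $MP / (0.098 \cdot LTC_{dyn}/1000)$, power per unit
  of *actually ventilated* lung volume — a stress-intensity surrogate.
  Algebraically this equals $RR \cdot P_{max} \cdot \Delta P_{aw}$
  (cmH2O²/min), an identity the test suite checks to 1e-9 relative
  tolerance.
* **Power index of the respiratory system**:
  $PI_{rs}^{k} = LTC_{dyn}\text{-}MP \times (\mathrm{PaCO_2}/45)^k$,
  rescaling stress intensity to isocapnic conditions at a 45 mmHg target so
  that patients ventilated at different rates and pressures become
  comparable. The exponent $k$ is an explicit argument; $k = 1$ and $k = 2$
  are the reported variants. The exponent's role is the package's own
  power-law reading of the superscripted index variants: it reproduces the
  reported cohort magnitudes (means near 5700 and 4600 cmH2O²/min for
  $k=1,2$) and has the isocapnic fixpoint $PI(x, 45, k) = x$ as a
  structural property.
* **Ventilatory ratio**
  $VR = (MV \cdot \mathrm{PaCO_2}) / (\mathrm{PBW} \times 100 \times 37.5)$,
  a dead-space surrogate equal to 1 for ideal lungs.

Higher values of every index go with SBT failure, so throughout the package
the positive class is *failure* and `score >= threshold` predicts it.

## Synthetic cohorts

Patient-level data from the motivating study are not public, so the package
ships a generator whose defaults encode the printed two-group structure:
100 successes and 30 failures (23.1 % failure); group-wise means ± SD for
tidal volume (547±83 / 547±97 mL), minute ventilation (9.0±2.0 / 9.0±1.7
L/min), PEEP (6.0±0.9 / 6.0±0.8), $P_{max}$ (22.8±4.1 / 26.3±3.5), PaCO2
(33.9±4.8 / 38.8±4.5 mmHg), PaO2, pH and FiO2; comorbidity prevalences
(COPD 16 %/46.7 %, smoking 29 %/63.3 %, malignancy 5 %/16.7 %); post-SBT
PaCO2 shifts of +2.4±4.4 (success) and +10.2±7.2 mmHg (failure); and seven
failure patients with a missing end-of-trial blood gas who fail on a vital
sign instead.

Design choices a user should know:

* **Truncated normals** (inverse-CDF draws, truncation at mean ± 3 SD
  unless a physiologic or screening bound is tighter — FiO2 in [0.21, 0.40],
  PEEP in [3, 8] cmH2O per the trial's screening criteria) keep every draw
  physiologic; `pmax` is redrawn until it exceeds PEEP by more than
  2 cmH2O.
* **Primitives first**: indices are never stored, always recomputed, so
  the algebraic identities hold on generated data and impossible
  combinations cannot arise.
* **Respiratory rate is derived** as $1000 \cdot MV / V_T$ because the
  source tables print MV and $V_T$ but not RR; this yields the implied mean
  rate (~16.5/min) and, importantly, the covariance that makes the mean of
  per-patient MP close to $0.098 \cdot \bar{MV} \cdot \bar{P}_{max}$.
* **Obesity is derived from BMI** (drawn per group with parameters chosen
  so that P(BMI ≥ 30) matches the printed 28 %/40 %) rather than drawn as an
  independent flag, keeping height, weight and the flag consistent.
* **Label consistency by construction**: failure records get a post-SBT
  PaCO2 above 45 mmHg or, when the drawn shift stays below that, tachypnoea
  above 35/min; success records are redrawn until all criteria clear. The
  generator verifies at the end that `classify_sbt_outcome()` reproduces
  every label and aborts otherwise.
* **Within-group independence**: the printed tables give no covariances, so
  primitives are drawn independently within a group apart from the
  structural couplings above (RR–MV–VT, BMI–mass–height). Consequently the
  *between*-group separation of the derived indices on synthetic cohorts is
  somewhat smaller than in the real cohort (where e.g. $P_{max}$ and PaCO2
  rise together in sicker patients): whole-cohort AUROCs for the power
  index near 0.76–0.78 rather than the published 0.81. Passing tests
  therefore demonstrate the pipeline's correctness and the indices'
  qualitative ordering (PI > LTC-MP > raw MP), not an exact reproduction of
  patient-level results.

`generate_logistic_cohort()` is the complement for the regression stage: an
index drawn from a stated normal and an outcome from a *known* logistic
mechanism, used for parameter-recovery tests where the truth must be exact.

## Diagnostic evaluation

`metric_set()` computes sensitivity, specificity, predictive values and
accuracy with Clopper–Pearson (exact binomial) 95 % intervals, the
likelihood ratios, diagnostic odds ratio, F1 and Matthews correlation
coefficient. Degenerate denominators follow fixed conventions: MCC and F1
are 0 when a marginal is empty; PLR/DOR may be infinite and are flagged,
never errors.

`roc_curve()` uses **attained score values as thresholds** (no midpoint
interpolation) so every operating point is auditable against the data; the
AUROC is the Mann–Whitney pair probability with ties counted one half, its
CI and test against 0.5 use DeLong's structural-components variance. The
suite cross-checks both the point estimate and the CI against an
independent reference implementation and against brute-force pair counting.
`optimal_threshold()` maximizes Youden's J with ties broken toward higher
specificity, comparing J in integer arithmetic so exact rational ties are
not broken by floating-point noise.

Cross-validation (`run_cv()`) is stratified, 2-times repeated, 2-fold by
default: folds balanced to within one patient overall *and* per class; the
threshold is learned on each training fold's ROC and applied unchanged to
the held-out fold ("prospective" in the structural sense — the test labels
cannot influence the threshold, a property the suite verifies by permuting
them). Metrics are aggregated as the unweighted mean over the k × repeats
test folds, and interval limits as the mean of the fold-level
Clopper–Pearson bounds; since other aggregations are defensible, the
per-fold records are kept in the result. Single-class test folds are excluded with a warning.

## Association models

`compare_groups()` operationalizes the "normality screen then t or U test"
rule as a Lilliefors-corrected Kolmogorov–Smirnov test at α = 0.05 per
group (Student's t with pooled variance when both pass, Mann–Whitney
otherwise); categorical variables use chi-square, or Fisher's exact test
when any expected cell is below 5. No multiplicity correction is applied,
matching the descriptive use of these tables.

`fit_logistic()` delegates the maximum-likelihood fit to `stats::glm`
(IRLS, convergence tolerance 1e-10, 50 iterations) and reports Wald 95 %
CIs for odds ratios on a caller-chosen unit scale — e.g. per 1000
cmH2O²/min for the power indices, the scale on which a unit OR of ~1.5 is
interpretable. Complete or quasi-complete separation is detected (IRLS
warning plus vanishing deviance) and raised as an explicit error.
Goodness-of-fit uses the Hosmer–Lemeshow decile test (bins merged with a
warning when fitted risks tie; error when fewer than three bins remain,
since the statistic would have no degrees of freedom) and Nagelkerke's R²
(Cox–Snell rescaled by its maximum, 0 for the intercept-only model).
`forward_select()` screens candidates univariably at p < 0.2, always admits
the a-priori set, then adds greedily by likelihood-ratio p-value with an
entry threshold of 0.05 (both thresholds configurable) and alphabetical
tie-breaks for determinism. `pearson_with_ci()` provides the Fisher-z correlation
interval used for index-versus-SBT-duration reports.

## Orchestration and reproducibility

`run_analysis()` chains the stages on a real (`read_cohort()`) or synthetic
cohort and writes the group-comparison, CV-metric, AUROC, regression and
correlation tables as full-precision CSV, a ROC comparison figure, and a
JSON record of the seed and configuration; identical seeds give
byte-identical tables, and every emitted number is recomputable from the
emitted cohort CSV alone. Missing post-SBT blood gases are handled by
complete-case analysis in the correlation stage and never block the
pre-SBT indices.

Problem sizes used in the automated checks: law-of-large-numbers moment
tests pool three cohorts of 10,000 per group; AUROC lower-bound
reproductions average 200 cohorts of n = 130; odds-ratio recovery uses a
single simulation of n = 5000 against its Wald interval.

## Limitations

The generator reproduces group-wise margins, not the full joint
distribution of a real ICU cohort (no longitudinal trajectories, no
inter-variable correlation beyond the structural couplings, no
multi-center heterogeneity), and the power-index exponent is a
reconstruction consistent with the reported magnitudes rather than a
verbatim-confirmed definition. Exact published patient-level statistics (AUROC 0.81,
multivariable odds ratios) are therefore targets of qualitative, not
numerical, reproduction.
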