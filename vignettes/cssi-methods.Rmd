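---
title: "CSSI: model, weighting and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSSI: model, weighting and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cssi)
```

## The index

The Confined-Space Suitability Index summarises a worker's physiological
readiness for confined-space work as a weighted sum of 13 dichotomous risk
factors. The design accepts a deliberate trade-off: dichotomising
continuous measurements loses information, but produces a screening rule
that is transparent, repeatable across examiners, and directly auditable
against the operational cutoffs. The index is a referral-support score, not
a fitness-for-duty decision: its intended use is prioritising workers for
specialist evaluation, which is why the negative predictive value at the
screening threshold matters more than the positive predictive value.

Three model layers are involved:

1. **Coding.** Each factor is a disjunction of printed clinical cutoffs
   (`code_risk_factors()`); operators are applied exactly as printed:
   inclusive `>=` for the obesity/hypertension/diabetes/dyslipidemia/
   smoking/alcohol thresholds, strict `>` for liver enzymes, the pure-tone
   average and tachycardia, strict `<` for bradycardia, anemia, the
   spirometry criteria and the VO2max reference bound. The total count maps
   to the rule-based category (0–3 suitable, 4–5 caution, ≥ 6 unsuitable),
   and the *unsuitable* indicator is the modelling outcome.
2. **Weighting.** An L1-penalized logistic regression of that outcome on
   the 13 flags, with age and sex as covariates, is fitted on a
   mean-imputed, z-scored design (`cssi_fit()`). The factor coefficients
   are truncated at zero and normalized to sum to one; covariate
   coefficients never enter the weights. The additive score is
   `100 * sum(w_i * flag_i)`.
3. **Validation.** Leave-one-out cross-validation re-runs the entire
   pipeline per fold and pools the held-out probabilities into AUROC,
   AUPRC and threshold-0.50 confusion metrics (`cssi_loocv()`); bootstrap
   resampling reports per-factor selection frequencies
   (`cssi_bootstrap()`).

### Assumptions worth stating

* The outcome the weights are trained on is itself *derived from the
  flags* (six or more factors). The LASSO therefore learns which factor
  combinations co-occur with high total burden in the sample at hand — a
  redistribution of emphasis among factors, not an association with an
  external clinical endpoint. This is inherent to the design, and it is
  why internal validation figures should be read as consistency checks,
  not as clinical accuracy.
* Weights estimated on z-scored predictors are applied to raw 0/1 flags.
  The two scales differ by a prevalence-dependent factor per column
  (1/sd of a binary column depends on its prevalence). We keep the
  coefficients "as calculated" and multiply by binary values because that
  is the published construction; users comparing factor weights should
  remember that low-prevalence factors are mildly up-weighted by this
  convention.
* Medication flags are taken as authoritative; a treated, well-controlled
  hypertensive still codes positive, which is intended (treatment signals
  the underlying condition).

## Tunable parameters

| parameter | default | units / range | notes |
|---|---|---|---|
| cutoffs (13 rules) | printed clinical values | clinical units | `cssi_cutoffs()`, YAML-overridable |
| VO2max reference | bundled placeholder bands | mL/kg/min, per sex, ~10-y bands | see below |
| `lambda` | `"auto"` | > 0 | penalty; auto = 5-fold stratified CV deviance minimum |
| `threshold` | 0.50 | probability | classification threshold on the model scale |
| `B` | 1000 | resamples | bootstrap stability |
| `sex_fraction_male` | 72/111 | proportion | generator |
| `miss_rate` | 0 | proportion | generator missingness injection |
| `correlation` | identity | PSD matrix | generator copula |

The VO2max reference deserves emphasis: the guideline tables the original
coding relied on (KOSHA H-43-2021, Canadian Public Health Association) are
cited but not printed anywhere we can redistribute, so the package ships
clearly-labelled synthetic placeholder bands
(`vo2max_reference_default()`, `inst/extdata/vo2max_reference_synthetic.yaml`)
in the range typical of published fitness classifications. Reproducing a
specific guideline's coding requires supplying that guideline's table.

The λ policy is likewise a documented gap-fill: no selection rule is
published, so the default is the conventional seeded stratified 5-fold
cross-validated deviance minimum, with a fixed numeric override for exact
reproducibility studies.

## The synthetic cohort generator

`generate_cohort()` emulates the published sex-stratified baseline table:
per-sex marginal means and SDs for 22 continuous variables, a 72/111 male
fraction, and Bernoulli medication/ECG flags. Medication prevalences are
not published; the defaults (antihypertensive 12 %/5 % M/F, antidiabetic
3 %, lipid-lowering 6 %/4 %) were chosen once as realistic for a
working-age East-Asian cohort and are config-overridable. The ECG flag
prevalence is set to the published coded prevalence (15.3 %/10.3 %),
since that flag *is* the risk factor.

**Marginals under physiologic bounds.** Several variables put substantial
normal mass below their floor (male pack-years 7.8 ± 11.2; female alcohol
frequency 0.3 ± 0.7). Sampling by rejection would shift the realised mean
far from the configured one (male pack-years would land near 12.4), and a
lower-truncated normal cannot represent a coefficient of variation above 1
at all. The generator therefore uses *moment-matched censored* normals:
for any variable whose clipped mass exceeds 5e-4, the latent mean and SD
are solved numerically (Nelder–Mead on the closed-form censored moments,
relative tolerance 1e-14) so that the clipped draw reproduces the
configured mean and SD exactly, with the clip producing a realistic point
mass at the floor (never-smokers at 0 pack-years). Dependence enters
through a Gaussian copula on the latent normals; the default correlation
is the identity because no joint structure is published, with a
`"realistic"` preset (BMI–waist r = 0.8, SBP–DBP r = 0.7, TC–LDL r = 0.85)
clearly labelled as non-study values.

**What passing tests do and do not show.** The generator matches marginal
moments, the sex split and plausible flag prevalences. It does *not*
reproduce the real cohort's joint distribution (risk factors cluster in
real workers far more than independent marginals allow), its exact coded
prevalences, or its category proportions. Pipeline results on synthetic
cohorts therefore validate the *machinery* — coding rules, weighting
arithmetic, leakage-free cross-validation, bootstrap bookkeeping — and
parameter recovery under known planted effects, not the published
cohort-specific estimates (category counts 86/19/6, AUROC 0.940, bootstrap
frequencies 0.981–0.850), which depend on non-deposited individual data.
Missingness injection is uniform at a configurable rate (default 0) and
never removes age, which anchors the VO2max banding.

## Numerical choices and degenerate inputs

* **Preprocessing.** Imputation means and z-score parameters are computed
  on training rows only and returned with the fit, so held-out rows are
  transformed without leakage (the LOOCV tests assert this with sentinel
  values). Zero-variance columns standardize to all-zeros, never NaN. An
  all-missing column imputes to 0 (which then standardizes to zeros).
* **Solver.** `glmnet` with `standardize = FALSE` (we standardize
  ourselves), intercept unpenalized. Fixed-λ coefficients use the exact
  refit, not path interpolation. `glmnet`'s small-class advisory is
  muffled — the unsuitable class is rare by design and the warning would
  otherwise fire on nearly every fold.
* **Degenerate fits.** If every factor coefficient is non-positive the
  weight set is all zeros with a hard warning rather than an error, so
  bootstrap resamples cannot crash the run. A LOOCV fold whose training
  outcome is single-class — or leaves fewer than two workers in a class,
  the solver's hard minimum — falls back to the training prevalence with
  a warning. Bootstrap resamples with fewer than two positives are
  redrawn (bounded retries, count reported). When the auto-λ policy meets
  a two-member minority class (possible in resamples), cross-validation is
  infeasible (every split would isolate a single member), and λ falls back
  to the deterministic BIC minimum along the penalty path.
* **Ties.** AUROC uses midranks (ties count one half); AUPRC groups tied
  probabilities as a single threshold step. Classification is
  `probability >= threshold`.
* **Rounding.** Reports round half-up to 3 decimals for display;
  `*_raw` JSON fields and all internal computation keep full precision.
* **Seeds.** Every stochastic stage (simulation, fold assignment,
  resampling) takes an explicit integer seed recorded in the artifacts'
  manifest; identical configurations reproduce byte-identical artifacts.

## Open design points, resolved

* *LOOCV scope.* The published description is ambiguous about whether
  weights were refit per fold. Refitting the whole pipeline per fold is
  the leakage-free reading and is the default; `refit = FALSE` scores
  held-out workers with one full-sample model for comparison. Neither is
  asserted to be the original computation.
* *Bootstrap "selected".* Interpreted as coefficient strictly positive,
  mirroring the positive-part weighting rule; `selection = "nonzero"`
  counts either sign.
* *Threshold scale.* The 0.50 threshold applies to the penalized-logistic
  probability, not the 0–100 additive score — 0.50 is only meaningful on
  the model scale.
* *Sex coding.* male = 1, female = 0 before standardization (arbitrary but
  fixed).
* *FEV₁/FVC scale.* Percent (0–100); an input validator rejects values
  that look ratio-scaled (0–1] to prevent silent cutoff mismatches.

## Problem sizes

The test suite and the acceptance script are sized for routine desk runs:
marginal calibration at n = 10,000; parameter-recovery at n = 2,000 over
50 seeded replicates; bootstrap separation at n = 500 with B = 200; the
end-to-end synthetic pipeline at n = 300 with B = 200 (large enough that
both outcome classes are reliably populated; at n ≈ 50 the unsuitable
class is frequently empty and the fit correctly refuses). The full-scale
study configuration (n = 111, B = 1,000) runs unchanged via
`run_pipeline()`.

## Known limitations

* Weights inherit the self-referential outcome noted above; external
  validation against an independent clinical standard is out of scope.
* The bundled VO2max bands are placeholders; coded low-fitness prevalence
  under them is plausible but not guideline-exact.
* The generator's independent-marginal default understates real risk-factor
  clustering; users studying joint-burden behaviour should supply a
  correlation matrix.
* Exact reproduction of published raw coefficient magnitudes is not
  promised: the λ policy, solver and tolerances of the original analysis
  are unpublished. The coefficient→weight normalization arithmetic, the
  category rule and the confusion arithmetic are exact and tested.
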