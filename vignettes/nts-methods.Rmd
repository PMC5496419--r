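---
title: "Methods: the New Trauma Score, its derivation machinery, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the New Trauma Score, its derivation machinery, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntscore)
```

## The problem and the scores

Physiological trauma scores summarise a patient's presentation — consciousness,
circulation, oxygenation — into a single number used for field and emergency
department (ED) triage and for mortality prediction. The Revised Trauma Score
(RTS) maps the Glasgow Coma Scale (GCS), systolic blood pressure (SBP) and
respiratory rate (RR) to integer code values 0–4 and combines them as

$$\mathrm{RTS} = 0.9368\,\mathrm{GCS_c} + 0.7326\,\mathrm{SBP_c} + 0.2908\,\mathrm{RR_c},$$

with a ceiling of 7.8408 at normal vitals. Three of its design choices have
aged poorly: the coded GCS discards information the raw score carries; the
SBP cut at 90 mmHg is lower than where mortality risk is now known to rise
(and ignores the excess mortality of hypertensive presentation, likely driven
by traumatic brain injury); and RR as measured at triage is unreliable, while
pulse oximetry is ubiquitous.

The New Trauma Score (NTS) addresses all three: it keeps the *actual* GCS
(3–15), recodes SBP with 110–149 mmHg as the reference band (code 4) and a
distinct hypertension band at ≥ 150 mmHg (code 3), and replaces RR with
peripheral oxygen saturation (SpO2) coded in five bands (≥ 94, 80–93, 60–79,
40–59, < 40 %). Fitting an in-hospital *survival* logistic model on these
three inputs gives

$$b = -6.5406 + 0.4006\,\mathrm{GCS} + 0.2983\,\mathrm{SBP_{NTS}} +
0.8709\,\mathrm{SpO_{2,NTS}}, \qquad P_s = \frac{1}{1 + e^{-b}},$$

so the NTS is the linear predictor without the intercept and $P_s$ the
predicted survival probability. Dropping the weights yields the triage sum
T-NTS $= \mathrm{GCS} + \mathrm{SBP_{NTS}} + \mathrm{SpO_{2,NTS}} \in [3, 23]$,
stratified as low (18–23), intermediate (12–17), high (6–11) and very high
(3–5) risk, with transfer to a trauma centre flagged at T-NTS < 18. MGAP and
GAP are included as point-additive comparators; their point tables are not
restated in the NTS publication and are frozen here from the scores' original
descriptions, with their own unit tests.

Modelling **survival** (not death) is a deliberate package-wide convention:
it makes all published signs consistent — vital-sign odds ratios above 1,
positive coefficients, $P_s$ a survival probability — and triage positivity
for death is then defined as *score below threshold*.

## Numerical conventions

**Interval boundaries.** The published code tables print integer endpoints
("76–89", "110–149"), leaving real-valued gaps. The package closes them with
half-open intervals anchored at the printed lower endpoints: each code's
interval is `[lower, next_lower)`, so SBP 89.5 codes RTS 3, SBP 149.5 codes
NTS 4, and RR 29.5 codes 4. This agrees with the printed tables on every
integer and is a package decision, not a statement of the source tables.
`coding_reference()` exports the realised intervals as JSON.

**Printed coefficients are canonical.** The published NTS range
(1.2019–10.6867) differs in the fourth decimal from arithmetic on the
published 4-decimal coefficients (1.2018–10.6858), implying unrounded
internal coefficients that were never printed. The package treats the
4-decimal coefficients as canonical and its tests require agreement with the
printed extremes only to $10^{-3}$.

**Non-measurable SpO2** is clinically informative (profound shock, arrest,
tamponade) and distinct from missing-at-random SpO2. Registries mark it with
the `NM` token; the coding layer maps it to code 0, the imputation layer
never imputes it, and the missing-at-random case stays `NA` until imputed.

**GAP's SBP bands.** Secondary sources disagree on whether exactly 120 mmHg
falls in GAP's upper or middle band; the package places 120 in the middle
band (`> 120` earns 6 points) and documents the choice in the constants'
tests.

## The synthetic trauma registry

No public trauma registry matches the single-hospital cohort the NTS was
derived on, so the package ships a calibrated generator
(`default_cohort_spec()`, `simulate_registry()`) that emulates the derivation
cohort's published marginals: n = 3263, median age 60 (IQR 46–73), 66.0 %
male, 94.4 % blunt, median SBP 130 (IQR 110–140), median RR 20 (18–20),
median GCS 15, median SpO2 98 (96–99), 11.3 % in-hospital mortality, and
missing-completely-at-random rates of 8.9 % (ISS), 3.2 % (SpO2) and 0.1 %
(SBP/RR/GCS).

Covariates are drawn from a **two-component mixture** rather than independent
marginals: a *stable* component (69.5 %) concentrated at normal vitals, and
an *injured* component (30.5 %) with depressed GCS, a 40 % hypoxic
subpopulation, and SBP dispersed over hypotensive, normotensive and
hypertensive (≥ 150 mmHg) regimes. The mixture makes abnormal vitals
co-occur — necessary for realistic score discrimination — and reproduces the
bimodal SBP–mortality relationship (mortality above 150 mmHg exceeding the
110–149 band) through the code-3-versus-4 gap in the outcome model, not an
extra term. The mixing weight 0.305 was calibrated once against the marginal
targets and the 11.3 % mortality rate, then frozen. Survival is drawn
Bernoulli($P_s$) from the published coefficients, so the generator's outcome
law *is* the published model: parameter-recovery tests have an exact oracle,
and the fitted model is well-specified by construction. Age is truncated
normal (60, 20) on [15, 105], which matches the published median and IQR;
ISS is a severity-correlated log-normal ordinal used only as an imputation
covariate and claims no anatomical meaning.

What the generator does **not** emulate: between-cohort drift (the published
validation cohort differs significantly in age, SBP and ISS), informative
missingness, measurement error in vitals, correlation of age or mechanism
with severity, and any anatomical injury structure. Passing tests therefore
demonstrate that the machinery is correct and well calibrated *under the
stated generating law*, not that the NTS's published cohort AUCs (0.935
derivation, 0.919 validation), odds-ratio tables or the 95 %-sensitivity /
82 %-specificity triage point are reproducible — those depend on the
unreleased hospital registry. On the synthetic cohort roughly half the
patients sit at the exact maximum score with ≈ 1.6 % mortality, so more than
5 % of deaths carry the top score and no finite threshold reaches 95 %
sensitivity; the operating-point machinery is instead verified against an
exhaustive threshold sweep.

## Imputation

`mice_pmm()` implements chained-equation multiple imputation with predictive
mean matching. Design choices, in the package's own words:

- **m = 10** completed datasets by default, following the rule of thumb that
  the number of imputations should reach the missingness percentage (maximum
  8.9 % here); **10 chained cycles**, a conventional length for a handful of
  variables.
- **Type-1 matching**: the donor metric compares observed predictions under
  the least-squares coefficients with missing-case predictions under
  coefficients perturbed by a posterior-style draw (σ² from the scaled
  inverse-χ², β* from N(β, σ²(XᵀX)⁻¹)), giving proper between-imputation
  variability. The donor pool is the **k = 5** nearest observed cases,
  drawn uniformly.
- Predictors are age, sex, the outcome, and the other vitals/ISS, matching
  the published imputation model; sex enters as an indicator, outcome as 0/1.
- Binary and categorical variables are never imputed (no missing outcome,
  sex or mechanism in the data model), and downstream score analyses run
  per-imputation with Rubin's rules (`pool_coefficients()`) reserved for
  regression coefficients — the source is silent on how its imputed datasets
  fed the ROC analyses, so this is a package decision.

PMM guarantees every imputed value is an observed donor value, so domains
and integer-ness are preserved by construction; under MCAR the imputed-cell
means are unbiased, which the test suite checks against the held-back truth
over 50 replicated registries.

## Statistical machinery

- **Logistic fitting** is IRLS via `stats::glm` behind the `fit_logistic()`
  surface, with covariance from the observed information. Separation is
  detected (diverging coefficients with fitted probabilities pinned at 0/1)
  and raised as an error; convergence tolerance and the 25-iteration cap are
  conventional choices.
- **AUC** uses the midrank (ties count ½) Mann–Whitney identity.
- **DeLong's test** for correlated ROC areas is implemented from placement
  values (structural components), with a two-sided normal z-test and a Wald
  interval on the AUC difference. When the two score vectors are identical
  the variance of the difference is zero and the test defines z = 0, p = 1.
  The implementation is cross-checked against an independent one (pROC) in
  the test suite and its type-I error is verified by a null Monte-Carlo
  (n = 500, 2000 replicates).
- **Hosmer–Lemeshow** groups by equal-count quantiles of the predictions
  with ties kept together, uses the classical χ² with g − 2 degrees of
  freedom, and errors on degenerate grouping rather than silently merging to
  one group. Its size is verified on well-specified fits at n = 3263 over
  500 replicates.
- **Operating points** sweep all observed thresholds plus +∞, define
  positivity as score < threshold, and return the maximal specificity among
  thresholds meeting the sensitivity target; the degenerate all-positive
  point is returned (flagged) when nothing else qualifies.
- **Cohort description** uses the Mann–Whitney U test (normal approximation,
  tie-corrected) for continuous and χ² without continuity correction for
  categorical variables; two-sided throughout, no multiplicity adjustment,
  matching how such tables are conventionally reported.
- Wald intervals are used wherever the source does not state the interval
  type.

## Problem sizes and determinism

Every stochastic routine takes an explicit integer seed, and the simulation
seed space is kept separate from the missingness-masking seed space (masking
derives its stream from `seed + 500009`) so that the mask is independent of
the covariate draws. The test suite sizes its Monte-Carlo studies to make
each check sharp but quick: parameter recovery at n = 200 000, mortality
calibration over 200 cohorts of n = 3263, DeLong size over 2000 null
replicates, Hosmer–Lemeshow size over 500 replicates, and imputation
recovery over 50 registries of n = 1000 — sizes chosen as the package's own
accuracy/runtime trade-off.

## Known limitations

- The coding boundary convention and the MGAP/GAP constants are frozen
  package decisions where the source is silent or external; both are
  isolated behind documented functions with exhaustive unit tests.
- The generator matches published marginals and the outcome law, not joint
  structure beyond the two-component mixture; effect sizes estimated on it
  should not be quoted as properties of any real cohort.
- Only adult (age ≥ 15), blunt/penetrating cohorts are modelled; there are
  no pediatric code tables.
- TRISS and anatomical (AIS/ISS-based) scoring are out of scope; ISS exists
  only as an imputation covariate.
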