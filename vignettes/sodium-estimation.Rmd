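---
title: "Estimating 24-hour sodium excretion from spot urine: models, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating 24-hour sodium excretion from spot urine: models, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natriuria)
library(dplyr)
```

## The problem

Salt intake matters clinically in chronic kidney disease (CKD): most CKD
patients are salt-sensitive, and high sodium intake accelerates
hypertension, albuminuria and disease progression. The reference method for
quantifying intake — the 24-hour urine collection — is burdensome and
error-prone, so single-void ("spot") urine samples are widely used as a
surrogate, combined with prediction equations that convert a spot sodium
concentration into an estimated daily excretion. Those equations (Kawasaki,
Tanaka, INTERSALT) were derived in populations with normal kidney function;
whether they transfer to CKD patients, whose sodium handling and circadian
excretion rhythm are altered and who are frequently on diuretics, is an
empirical question.

`natriuria` implements the three equations exactly as published, the
protocol rules for screening and time-correcting 24h collections, and the
agreement and diagnostic statistics used to validate spot-urine estimates
against measured collections. Because the patient-level data of the
motivating cohort study are access-restricted, the package also ships a
seedable synthetic cohort generator calibrated to that study's published
summary statistics, so every stage of the pipeline is exercisable and
testable end to end.

## The estimation equations

All three equations return an estimated 24h sodium excretion in mg/d; the
final factor 23 (mg per mmol, the rounded molar mass used in the published
forms) converts mmol/d to mg/d. Spot concentrations are denoted
$U_{Na}, U_K$ (mmol/l) and $U_{crea}$ (mg/dl for Kawasaki/Tanaka, mmol/l
for INTERSALT; `convert_creatinine()` bridges the two using creatinine's
molar mass, 113.12 g/mol).

**Kawasaki** (second-morning urine only), sex-specific:
$$ 23 \times 16.3 \times \sqrt{\frac{U_{Na}}{10\,U_{crea}} \times B_s},
\qquad
B_{male} = 15.12\,w + 7.39\,h - 12.63\,a - 79.9, $$
$$ B_{female} = 8.58\,w + 5.09\,h - 4.72\,a - 74.5 $$
with weight $w$ (kg), height $h$ (cm), age $a$ (years). The $\times 10$
inside the ratio converts creatinine mg/dl to mg/l; it is kept literally
as printed so the code audits line by line against the published table.

**Tanaka** (any spot timing), one form for both sexes:
$$ 23 \times 21.98 \times \left(\frac{U_{Na}}{10\,U_{crea}}
   \times (-2.04\,a + 14.89\,w + 16.14\,h - 2244.45)\right)^{0.392}. $$

**INTERSALT**, sex-specific linear predictors in mmol/d (women with a
quadratic age term):
$$ \textrm{men: } 25.46 + 0.46\,U_{Na} - 2.75\,U_{crea} - 0.13\,U_K
   + 4.10\,\textrm{BMI} + 0.26\,a $$
$$ \textrm{women: } 5.07 + 0.34\,U_{Na} - 2.16\,U_{crea} - 0.09\,U_K
   + 2.39\,\textrm{BMI} + 2.35\,a - 0.03\,a^2. $$

Three behavioural decisions, visible in `estimate_sodium()`:

* **Negative INTERSALT estimates are flagged, not clamped.** For very
  dilute urine the linear predictor can go negative. Clamping to zero
  would shift the Bland–Altman bias; the validation statistics must see
  the estimator as defined.
* **Kawasaki is refused evening (PM) samples by default.** The equation
  was derived for morning voids. An explicit `allow_kawasaki_pm = TRUE`
  computes the value anyway and flags it `ineligible_timing`, for
  exploratory use.
* **Supplied BMI wins over the derived one.** BMI enters INTERSALT
  directly; when it is absent it is derived as $w/(h/100)^2$, but a
  recorded BMI (which may come from a different visit than the recorded
  weight) is never overridden.

Sodium mass converts to salt (NaCl) mass via exact molar masses,
$58.443/22.98977 = 2.542$ — the conventional 2.54 g salt per g sodium.
The guideline intake limits of 5 and 10 g/d salt therefore correspond to
the 2 and 4 g/d sodium thresholds used in the classification grid.

## Collection preprocessing

The study protocol accepts a 24h collection when its duration lies in
[20, 28] h and its volume, as a daily rate, is at least 250 ml/d.
`screen_collections()` applies exactly that: the volume is compared
*after* normalisation to 24 h (the protocol states a daily rate), and
boundary values are accepted because the rules are phrased as strictly
"below"/"above". `normalize_collections()` converts concentrations into
daily totals (concentration × volume / 1000) and rescales totals linearly
by $24/\textrm{duration}$. Linear rescaling is the simplest defensible
reading of "corrected to 24 h" used by the population-survey methodology
the protocol references; it is isolated in one function so an alternative
correction could be swapped in. Only totals are affected — concentrations
are ratios and invariant under the rescaling — which is why the choice of
rescaling totals rather than concentrations is immaterial to every
downstream quantity the package uses.

Missing spot samples (e.g. a participant who provided only the morning
void) propagate as missing values into pairwise-complete analyses; nothing
is imputed.

## Statistics

**Spearman correlation** is computed as the Pearson correlation of average
(midrank) ranks, with the two-sided p-value from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom — the
approximation mainstream statistical software uses at these sample sizes.
Constant vectors make the coefficient undefined and are reported as `NA`
with a warning, never coerced to 0.

**Fisher-Z comparison.** Two correlations from independent samples are
compared by
$Z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\,/\,
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. Two points deserve emphasis. First, the
package reports the one-sided p-value $\Phi(-|Z|)$ as primary and the
two-sided value alongside: the one-sided convention is what the motivating
study's printed p-values follow throughout, and reproducing those numbers
exactly is one of the package's calibration checks. Second, the
independent-samples formula is applied even when the two correlations
involve the same participants (AM vs PM timings): this matches the
published analysis. A dependent-correlations test (Steiger) would be the
statistically stricter choice and is deliberately out of scope.

**Bland–Altman agreement.** Differences are defined as measured −
estimated, so a *positive* bias means the equation *underestimates*
excretion. The limits of agreement are bias ± 1.96 × SD of the
differences (sample SD, $n-1$). The significance of the bias is a
one-sample t-test of the differences against zero — the motivating
analysis does not name its test, and this is the conventional choice.
When the differences are constant the test is undefined and `bias_p` is
`NA`.

**P30** is the percentage of estimates within ±30% of the measured value,
boundary inclusive.

**Classification** dichotomises measured and estimated daily sodium at a
threshold using strict `>`, per the published definitions, and reports
sensitivity, specificity, PPV and NPV as percentages. A metric whose
denominator is empty (e.g. sensitivity when nobody measures above
threshold) is `NA`, never 0 — small strata must degrade to missingness,
not to fake certainty.

## The synthetic cohort generator

`simulate_cohort()` emulates the cohort the motivating study describes:
108 participants (66 men), age 62.2 ± 11.9 y within the 19–74 y enrolment
window, BMI 29.7 ± 6.2 kg/m², serum creatinine 1.56 ± 0.5 mg/dl (placing
the cohort around CKD stage G3), 54.6% diuretic use, collection time
24.2 ± 1 h in [20.8, 26.7] h, recorded volume averaging 2511 ml in
[500, 6500] ml, and 24h sodium excretion in [19, 437] mmol/d with mean
≈183 mmol/d (the value implied by the reported average salt intake of
10.7 g/d: $10.7 / 2.542 / 23 \times 1000$). The serum sodium summary
(145 ± 4.8 mmol/l) is carried in the configuration for completeness but
feeds nothing downstream.

Mechanism, in sampling order:

* **Bounded marginals are moment-matched.** BMI, serum creatinine,
  height and duration are truncated normals whose *parent* parameters are
  solved numerically so the truncated distribution has exactly the
  configured mean and SD; sampling is by quantile inversion (no rejection,
  no boundary atoms). Age is the one exception: on [19, 74] no truncated
  normal attains mean 62.2 *and* SD 11.9 (the window clips too much upper
  tail — the family maxes out near SD 11.2 at that mean), so age uses a
  scaled Beta on the window, moment-matched exactly. The Beta is
  right-skewed toward the enrolment cap, which is also what an age-capped
  CKD cohort looks like.
* **24h excretion and volume are truncated lognormals**, again with the
  log-scale location solved so the truncated mean hits the configured
  mean. Inversion-truncation leaves no ties at the range limits.
* **Spot concentrations are copula-linked to daily excretion.** A latent
  standard normal $z_{24}$ drives excretion through its quantile
  transform; the AM and PM spot-sodium latents are
  $\rho^* z_{24} + \sqrt{1-\rho^{*2}}\,\varepsilon$ with
  $\rho^* = 2\sin(\pi\rho_s/6)$, the classical conversion from a target
  Spearman $\rho_s$ to the Gaussian-copula parameter. Because every
  marginal transform is strictly monotone, the population Spearman
  correlation between a spot concentration and daily excretion equals the
  target exactly (0.234 for AM, 0.463 for PM by default). The spot-sodium
  marginal is lognormal with median `na24_mean / vol_mean`, i.e. on the
  excretion-per-volume scale.
* **Spot creatinine and potassium** derive from daily excretion divided
  by daily urine volume with multiplicative lognormal "circadian" noise.
  Daily creatinine generation is 20 mg/kg/d (men) / 15 mg/kg/d (women),
  attenuated 2%/year after age 50 and floored at 30% — standard
  physiology, kept in the configuration so nothing else depends on it.
* **Internal consistency.** The recorded 24h concentrations are defined
  so that `normalize_collections()` recovers the latent daily excretion
  (up to output rounding), and eGFR comes from the sampled serum
  creatinine, age and sex through the four-variable MDRD equation
  ($175 \times Scr^{-1.154} \times age^{-0.203} \times 0.742$ if female
  — the 175-based coefficient set, a deliberate implementation choice
  since only the formula family is fixed by the protocol), so CKD strata
  are consistent with the demographics rather than sampled independently.
  Sex counts are fixed at `round(n * frac_male)` so the default cohort
  reproduces the 66/42 composition exactly; diuretic use stays Bernoulli.

**What the generator does and does not emulate.** It reproduces marginal
summary statistics and one targeted dependence (spot concentration vs
daily excretion). It does not model day-to-day intake variation, infradian
excretion rhythms, the dependence of spot-to-24h concordance on CKD stage
or diuretic class, measurement error in the laboratory assays, or
incomplete collections. Consequently, pipeline results on synthetic
cohorts validate the *machinery* — screening, normalisation, estimation,
agreement statistics, stratification — not the clinical conclusions;
synthetic agreement statistics (biases, P30, classification metrics) will
not and should not match the published patient-data values.

## Numerical choices and degenerate inputs

* Estimation refuses non-positive spot creatinine and anthropometry that
  drives a body-size term non-positive (domain errors), and `una = 0`
  yields exactly 0 for the power-form equations.
* The moment-matching solvers (`optim` on parent mean/log-SD, `uniroot`
  for lognormal locations) run to tolerances far below output rounding;
  infeasible moment/bound combinations are errors, not silent
  approximations.
* Strata or cells with fewer than `min_n` (default 4) complete pairs are
  reported as missing cells, so small cohorts run without failure; the
  Kawasaki–PM cell is structurally present but always `NA`.
* Simulation draws use quantile inversion from a single `set.seed(seed)`
  stream with a fixed draw order, giving bit-for-bit reproducibility; the
  caller's RNG state is saved and restored.
* Reports serialise with full double precision (`digits = NA`), making
  repeated runs byte-identical.

## Problem sizes used in the test suite

The suite validates the equations against an independently coded
arithmetic path (log-space / reordered summation) to ten significant
digits on 1000 random physiological inputs; Spearman against a brute-force
$O(n^2)$ counting oracle exhaustively on all pairs of length-3 vectors
over {1..4} plus 500 random longer tied vectors; Bland–Altman coverage on
$10^5$ normal differences (95% ± 2%); the PPV/Bayes identity on 200
random confusion tables; and generator recovery at n = 5000 (rank
correlations within ±0.03, demographic moments within ±3% relative).
These sizes keep the full suite under a minute while leaving each check
with comfortable statistical resolution.

## A worked run

```{r example}
cohort <- simulate_cohort(n = 108, seed = 1)
report <- run_analysis(cohort)
report$agreement |>
  select(formula, timing, n, rho, mean_bias, loa_lower, loa_upper, p30)
glance(report)
```

The Fisher-Z machinery applied to published correlation pairs (the
printed r and n are inputs; the Z is computed):

```{r fisherz}
fisher_z_compare(0.234, 108, 0.463, 107, labels = c("AM", "PM"))
```

## Known limitations

* The equations are reproduced as printed, including their rounded
  constants; no recalibration to CKD populations is attempted (and the
  motivating literature suggests recalibration, not reimplementation, is
  where the real gain lies).
* The Fisher-Z comparison treats AM/PM correlations from the same
  patients as independent (see above); p-values for those comparisons are
  anti-conservative in principle.
* ROC analysis and alternative estimators (Mage, Whitton, …) are out of
  scope; the classification grid evaluates the fixed guideline thresholds
  only.
* The generator's copula targets a single global rank correlation; it
  cannot express stratum-specific concordance differences, so stratified
  Fisher-Z comparisons on synthetic data hover around zero by design.
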