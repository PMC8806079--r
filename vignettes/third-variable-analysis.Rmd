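---
title: "Third-variable analysis of the cotinine-telomere association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Third-variable analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsupp)
```

## The scientific problem

Tobacco smoking is associated with shorter leukocyte telomere length
(LTL), but reported effect sizes are inconsistent across cohorts. One
plausible source of inconsistency is the behaviour of *third variables*
that sit on or near the causal path between smoke exposure and telomere
attrition. Two candidates act in opposite directions: smoking lowers body
weight while low BMI predicts longer telomeres, so the weight pathway can
*mask* part of the exposure-outcome association (suppression); smoking
raises systemic inflammation (CRP) while inflammation predicts shorter
telomeres, so the inflammatory pathway can *carry* part of it (mediation).
`medsupp` quantifies both phenomena with one decomposition, using serum
cotinine — an objective biomarker of recent active or passive smoke
exposure — as the predictor.

## The decomposition and its assumptions

Let X be log cotinine, Y LTL in base pairs, Z₁…Z_K (K ≤ 2) the third
variables, and W the covariates (age, race, sex, physical activity,
alcohol use). Three ordinary-least-squares models are fit **on one shared
complete-case sample**:

* total: Y ~ X + W, giving the standardized total effect c;
* exposure paths: Zₖ ~ X + W (other Zs excluded), giving β₁ₖ;
* outcome: Y ~ X + Z₁ [+ Z₂] + W, giving the direct effect c′ and the
  adjusted outcome paths β₂ₖ.

Standardization multiplies each raw coefficient by SD(term)/SD(Y), with
n−1 SDs recorded at design construction; binary indicators are scaled
like continuous terms so all effects share one unit. Because the three
models are nested projections on the same rows and the same scalings,

c = c′ + Σₖ β₁ₖ β₂ₖ

holds *algebraically*, not just asymptotically; the pipeline enforces it
to 1e-10 and treats violation as an internal error (it can only happen if
sub-models silently used different samples, which the shared-design
architecture rules out).

The interpretation of β₁ₖβ₂ₖ as an indirect *effect* — rather than a
regression artefact — leans on the usual structural assumptions:
linearity, no unmodelled exposure-intermediate or intermediate-outcome
confounding, and no X×Z interaction on Y. The package makes the weaker,
purely statistical claims testable (the identity, the delta-method
calibration) and leaves the causal reading to the analyst.

### Classification and percentages

With a single Z and |c| > |β_Ind|, the rule compares magnitudes:
mediation if |c| > |c′| (percentage |β_Ind|/|c|·100), suppression if
|c| < |c′| (percentage |β_Ind|/|c′|·100). Two boundary cases are not
covered by the published rule and are fixed deterministically here:
|c| ≤ |β_Ind| returns `"undefined"` (with an `NA` percentage and a
warning), and the measure-zero tie |c| = |c′| resolves to mediation when
the indirect effect has the sign of c, suppression otherwise. With two
Zs the |c|-vs-|c′| comparison is no longer per-variable, so per-Z roles
are assigned by the sign relationship of each component to the total
effect: a component aligned with c carries part of it (mediation-type), a
component opposing c masks part of it (suppression-type). Percentages are
computed from unrounded values and only rounded for display (1 decimal).

### Indirect-effect inference

The Sobel-type test uses the first-order delta-method standard error
√(β₁²se₂² + β₂²se₁²) on the standardized coefficients, with a two-sided
normal reference; the second-order variant (adding se₁²se₂²) is available
via `second_order_sobel`. For the two-Z overall indirect effect the two
component variances are summed, ignoring their cross-model covariance —
exact for one Z, a first-order approximation for two. The product-of-
coefficients test is known to be conservative near β₂ = 0; the calibration
suite measures a type-I error of about 0.04 at α = 0.05, n = 500, inside
the accepted [0.03, 0.07] band.

Whether the original analysis ran its indirect-effect test on raw or
standardized coefficients is not documented; standardized coefficients
are used here because every other reported quantity is standardized, and
the z statistic is invariant to the common SD(Y) rescaling of β₂ and c′.

## Tunable parameters that matter

* `lod_policy` — below-detection biomarker handling before the natural-log
  transform: `lod_over_sqrt2` (default, LOD/√2, standard single-limit
  exposure-science practice), `half_lod`, or `strict` (refuse). Every
  substitution is counted and surfaced in the run log. The log base is
  natural; base choice only rescales the log column and cancels out of
  standardized coefficients.
* Covariate coding — race→black(0/1), sex→female(0/1), physical activity
  →any-activity(0/1), alcohol→ordinal 0–3, smoking→0/1. Activity is a
  single indicator and alcohol a single ordinal score because the target
  analysis reports one coefficient for each; whether the original
  alcohol covariate was ordinal or binary is undocumented — ordinal is
  the package's choice, flagged here.
* `min_group_n` (default 50) — smallest stratum accepted by
  `interaction_test`.
* T/S↔bp conversion — LTL = 3274 + 2413 × T/S, applied when a cohort
  carries only the qPCR ratio.

## The synthetic generator: what it emulates, what it does not

`generate_cohort()` draws from an explicit linear-Gaussian structural
model: demographics at fixed NHANES-like frequencies (47.4% female, 23.1%
Black, 27.0% current smokers, age uniform 20–85); log cotinine as a
two-component mixture (non-smokers centred at 0.2 ng/mL near the
0.05 ng/mL LOD, smokers shifted by 6.62 log units, common SD 1.1); BMI,
log CRP and LTL from linear equations with Gaussian errors. Path
strengths are *specified on the standardized scale* and converted
internally to raw coefficients using the known source variances, so the
population standardized partial coefficients equal the requested values
exactly — no tuning loop. The defaults reproduce the published
dual-intermediate coefficients (β₁ = −0.079/+0.109, β₂ = −0.036/−0.061,
c′ = −0.0448, hence c = −0.048605) and the age/race/sex/activity/alcohol
coefficients of the outcome model; `scripts/generator_calibration.R`
verifies that fitted values at n = 4,047 land within ±0.02 of them.

`implied_standardized_paths()` is the oracle: it assembles the population
covariance matrix from the structural loadings (exact for the Bernoulli
and uniform sources — no normality needed, least-squares projections
depend only on second moments) and solves each sub-model's normal
equations analytically. Its values satisfy the decomposition identity to
machine precision.

Deliberate simplifications, and hence what a green test does **not**
establish:

* No BMI→CRP structural path. Consequently the single-Z β₂ values
  coincide with the dual-model ones, unlike real cohorts where adiposity
  drives CRP and single-Z coefficients are larger in magnitude. The
  qualitative suppression/mediation pattern is unaffected; tests that
  compare single-Z magnitudes to published single-Z tables would not be
  meaningful and are not made.
* LOD censoring (~8% of non-smoker cotinine) is applied by the generator
  but ignored by the oracle. The LOD/√2 substitution perturbs the
  numerator and denominator of each standardized coefficient almost
  identically; at n = 10⁶ every fitted path sits within one Monte-Carlo
  SE of the uncensored oracle, so the approximation is far below test
  resolution.
* BMI is winsorized to (10.1, 79.9) kg/m² (~0.2% of draws) and LTL
  floored at 3,300 bp (~10⁻⁴%) so every generated row passes the validity
  invariants; both bounds are >2.8 SD from the mean.
* Values are rounded to laboratory precision (age/BMI 0.1, LTL 1 bp,
  biomarkers 4 significant digits); the added quantization noise is
  orders of magnitude below the structural noise.
* No survey design: the generator draws i.i.d. rows. The original survey
  is multistage and weighted; the published analysis did not use weights,
  and neither does this package. Estimates are conditional associations
  in the stated superpopulation, not design-based population estimates.

The generator emulates a *null of convenience* for calibration runs by
zeroing path sets (see `null_params()` in the test helpers), and any
path can be re-specified per run, e.g. β₂ = 0 for the Sobel type-I study.

## Numerical choices

* OLS by pivoted QR; rank deficiency is an error naming the offending
  column, never a silent drop. Classical homoskedastic SEs with t
  inference on the residual df (robust variance is out of scope; at
  n ≈ 4,000 the normal/t distinction is immaterial but t is exact under
  the model).
* CI/p coherence: confidence limits and p-values use the same t
  reference, so p < 0.05 exactly when the 95% CI excludes zero.
* Degenerate scales (constant columns) error before model fitting, at
  design construction, so the failure names the variable rather than the
  algebra.
* CSV round-trips write numerics with 15 significant digits, escalating
  to 17 only when needed for bit-exact re-reading; below-LOD entries are
  `"<0.05"`-style strings, missing values empty cells.
* RNG: one seeded stream per cohort with a documented fixed draw order;
  identical params + seed give byte-identical CSVs.

## Known limitations

* Cross-sectional associations only; no longitudinal attrition model.
* At most two third variables; no bootstrap CIs for indirect effects
  (the delta-method SE is the only interval source); no E-value style
  sensitivity analysis.
* Group comparisons are binary-only; multi-level race comparisons must be
  reduced to pairwise contrasts upstream.
* The per-Z role convention in the dual model (sign attribution) is a
  stated convention, not an identified causal quantity.
* Below-LOD handling is substitution-based; censored-likelihood
  estimation is not implemented.

Every empirical number quoted above (oracle agreement, calibration band,
censoring impact) is recomputed by the test suite
(`tests/testthat/test-acceptance.R`) or by the scripts in `scripts/`;
none is asserted from memory.
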