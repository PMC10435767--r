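---
title: "The IgG glycan ageing clock: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IgG glycan ageing clock: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(glycanclock)
library(dplyr)
```

## The scientific problem

Immunoglobulin G carries N-glycans whose composition changes with age in a
highly reproducible way: glycans without galactose (G0) rise, digalactosylated
(G2) and sialylated (S) glycans fall. These shifts are among the strongest
known molecular markers of biological ageing. In a case-control design —
here, adults with Down syndrome (DS, trisomy 21) versus age- and sex-matched
euploid controls — two questions arise:

1. **How much "older" is the case group's glycome?** If a trait follows a
   linear age trend in both groups and the case curve is vertically offset,
   the offset can be re-expressed on the age axis: the *glycan-age shift*
   is the number of years one must add to a control's age for their expected
   trait level to match a case of the same chronological age.
2. **Does the *rate* of glycan ageing differ?** An "amplified instability"
   model predicts case and control curves that diverge with age; parallel
   curves (equal slopes) contradict it.

`glycanclock` implements the full analysis pipeline for these questions,
plus a synthetic-cohort generator so that every stage can be validated
against known ground truth without access to clinical samples.

## Pipeline model, stage by stage

### Normalization and batch correction

UHPLC chromatograms are integrated into 24 peaks (GP1–GP24). Raw areas are
divided by the total chromatogram area (`normalize_total_area()`), making
each row a composition summing to 100%. Because plate (batch) effects act
multiplicatively and the peak distributions are right-skewed, correction
operates on natural logs (`log_transform_peaks()`).

`batch_correct()` implements the parametric empirical-Bayes
location–scale model (the ComBat model): per peak, data are standardized
using a covariate model; per-plate additive (γ) and multiplicative (δ)
effects are estimated and shrunk toward pooled priors via the standard EB
moment equations, then removed. The function returns the full fitted
`batch_model` (raw and shrunken γ/δ per plate and peak, prior
hyperparameters), inspectable with `tidy()`/`glance()`.

Two open choices had to be fixed:

* **Covariates in the EB model.** The biological covariates (`group`,
  `age`, `sex`) are included by default. On a blocked, balanced design the
  choice is nearly irrelevant; off-design, preserving biology is the safer
  default. A confounded design (a plate perfectly aligned with a preserved
  covariate) is rejected with a diagnostic rather than silently absorbed.
* **Scale on which derived traits are computed.** Corrected values are
  exponentiated back to the percentage scale before the trait sums
  (`as_percent_scale()`, done automatically by `derived_traits()`),
  keeping the published formulas dimensionally meaningful.

### Peak exclusion and derived traits

GP20 and GP21 co-elute on some plates and are excluded post hoc
(`exclude_peaks()`, no renormalization), leaving 22 measured variables.
Six derived traits are then computed as fixed sums of member peaks
(`trait_formulas()`): G0 (agalactosylated), G1, G2 (mono-/digalactosylated),
S (sialylated), F (core-fucosylated, 14 terms) and B (bisecting GlcNAc,
9 terms). GP5 enters no formula.

### Standardization and association models

Before association testing, every variable is transformed to a standard
normal by the rank-based inverse-normal transform
(`rank_inverse_normal()`): average ranks, then
$\Phi^{-1}((r - 0.5)/n)$. This makes effect sizes comparable across cohorts
of different size — all transformed variables have the same variance. The
offset 0.5 is the package default; the Blom variant (3/8) is available via
the `offset` argument.

Per cohort, `fit_glm()` estimates the standardized group effect by OLS of
the transformed trait on the case indicator, age and sex. Co-morbidity
subgroup contrasts reuse the same operation on filtered data. Sibling pairs
are handled by `fit_paired()`, a linear mixed model with a family random
intercept (REML via lme4/lmerTest; a zero variance component is allowed and
collapses to OLS). Cohorts are pooled by inverse-variance fixed-effects
meta-analysis (`meta_fixed()`), and the pooled p-values are adjusted
across the trait family by Benjamini–Hochberg (`bh_adjust()`). The BH
family is all traits tested within one analysis run, applied per contrast.

### Age trends and the glycan-age shift

Trend fitting uses *raw-percentage* traits, not rank-transformed values
(the shift is interpreted in trait units against age). Within each cohort
and group, `fit_trend()` fits trait = a·age + b. The rate-of-ageing
question is answered by `test_parallel_slopes()`: a single model with a
group×age interaction.

Given case and control fits, `age_shift()` maps the case expectation onto
the control curve:

$$\Delta(x) = \frac{a_{DS}\,x + b_{DS} - b_{ctrl}}{a_{ctrl}} - x,$$

the control age whose expected level equals the case expectation at age
x, minus x. For exactly parallel lines this is the constant
$(b_{DS}-b_{ctrl})/a_{ctrl}$. Three conventions:

* **Direction.** The case expectation is mapped onto the control curve, not
  the reverse; for near-parallel lines the two differ by
  $O(\Delta\,|a_{DS}-a_{ctrl}|/a_{ctrl})$.
* **Sign.** A trait that rises with age and is elevated in cases, and a
  trait that falls with age and is reduced in cases, both give a positive
  shift ("biologically older").
* **Grid.** The shift is averaged over the integer ages spanning the
  intersection of the two groups' observed age ranges. For parallel lines
  the grid is irrelevant; for nearly-parallel lines it matters only in the
  second decimal. Exact grid endpoints are therefore not treated as a
  reproducible quantity — the per-cohort and cross-cohort averages are.

`combine_shifts()` averages per-cohort mean shifts with equal weights
(each cohort contributes one population-level estimate; inverse-variance
weighting is deliberately *not* used here as the per-cohort averages are
the quantity of interest, not a common-effect estimate).
`bootstrap_shift_ci()` provides percentile intervals by resampling
subjects within group within cohort.

Degenerate configurations fail loudly: a control slope below 1e-6 in
magnitude or slopes of opposite sign leave the shift undefined.

### PCA placement of a singleton

`fit_pca()` performs correlation-matrix PCA (standardized scale) with a
deterministic sign convention (the largest-magnitude loading of each
component is positive), so results are reproducible across platforms.
`project_and_assign()` standardizes a held-out sample with the training
means/SDs, projects it onto the first k components (default k = 3,
matching the PC1–PC3 views usually inspected) and assigns it to the nearest
group centroid in that space, reporting all centroid distances. The
singleton is excluded from the PCA fit by default and projected afterwards;
a switch (`include_singleton_in_fit`) exists because published analyses are
often ambiguous on this point. Orthogonal noise directions add equally to
both centroid distances, so the assignment is effectively driven by the
discriminant direction.

## The synthetic cohort generator

`simulate_cohort()` generates peak tables whose *statistical structure*
matches what the analysis assumes, with full ground truth recorded:

* **Controlled traits.** Latent G0, G1 and G2 follow configured linear age
  trends per group. The default lines for G0 and G2 are the fitted
  trendline coefficients of the three adult study cohorts (e.g. FRA
  control G0: 0.43·age + 6.72); G1, for which no lines are published, uses
  a flat, slightly negative default (slope −0.05; intercepts 38/37.2)
  chosen to keep the composition feasible and the implied pooled G1 effect
  small and negative.
* **Closure.** S is the buffer: S = 100 − fixed − G0 − G1 − G2, with small
  fixed fractions for GP5 (1%), GP20 and GP21 (0.5% each). This guarantees
  exact compositional closure while the three headline traits follow their
  lines; consequently F and B are *not* independently controllable — they
  emerge from the peak-split weights. An infeasible configuration (trait
  means leaving no room for S at some age) fails naming the offending age.
* **Peak split.** Each trait total is distributed over its member peaks by
  weights shaped like a typical adult IgG glycome (GP4 dominating G0, GP8/9
  dominating G1, GP14 dominating G2, GP18 dominating S). These are artifact
  defaults, not estimates of any real cohort.
* **Noise.** Three layers: additive Gaussian noise on the latent traits
  (biological variation; defaults 4.0/3.5/3.5% for G0/G1/G2 in adults),
  lognormal multiplicative noise per peak (technical variation, log-SD
  0.05) and lognormal multiplicative plate effects (log-SD 0.05) shared by
  all samples on a plate. Rows are renormalized to 100 afterwards. Latent
  traits and S are floored at 0.5% so peaks stay positive; the floor count
  is recorded in the ground truth.
* **Cohort structure.** Default specifications reproduce the three adult
  study populations (sizes 109+98, 53+57, 42+53; their age ranges, sex
  ratios and co-morbidity fractions), a 35-pair sibling sub-cohort in the
  Italian population (shared family random intercept, SD 2%), and seven
  shared collection plates with balanced assignment.
* **Determinism.** One master seed; every sub-stream (metadata, trait
  noise, peak noise, plate effects) is derived from it, so identical calls
  give identical tables.

### Calibrated standardized effects

For parameter-recovery studies the generator can be asked for a *target
standardized group effect* instead of explicit case lines
(`effect_size = c(G0 = 0.72)`). Because the rank-INT transform compresses
large separations (its group contrast saturates near the theoretical
maximum for the group sizes), a linear SD-based conversion would be
biased. `calibrate_group_offset()` instead root-finds the raw offset d
such that the group coefficient of the analysis model on the transformed
latent sample equals the target exactly — the calibration therefore
accounts for the transform's nonlinearity by construction. Downstream
peak-level noise and renormalization add only ~1% attenuation.

### The children cohort

`simulate_children()` emulates the early-childhood comparison: 38 DS
children (ages 0.58–5.25), 17 controls (ages 3–5), and optionally one
extra sample labelled `"segmental"` — a child whose trisomy covers only a
chromosome-21 segment but whose glycome follows the DS distribution.
Children are modelled as a group comparison with flat latent means (the
adult control/case lines evaluated at age 4), not as trends: no child
trend lines are published, adult slopes have no support in toddlers, and
the published childhood results are group contrasts. Child noise SD is
0.8% per trait — toddlers' narrow age span and limited environmental
exposure make their glycome much less variable than adults' — which makes
the case and control G0 ranges essentially disjoint, as reported for this
age group. Under these conditions the segmental singleton projects into
the DS cluster in ≈99% of replicates.

### What the generator does and does not emulate

It reproduces: compositional closure, linear age trends with group
offsets, multiplicative plate effects handled on the log scale, sibling
correlation, co-morbidity flag frequencies, and cohort sizes/age ranges.
It does **not** reproduce: real peak-level composition (weights are
artifact defaults), independent F/B group effects (closure makes them
derived quantities), non-linear age trends, age-dependent variance, or
correlated co-morbidities. Passing tests therefore demonstrate the
*estimators* are correct and calibrated under the assumed structure — not
that the assumed structure exhausts real data.

## Numerical choices

* Rank-INT ties get average ranks; fewer than 3 values or all-equal input
  is an error rather than a silent constant.
* The EB iteration stops when the relative change of γ* and δ* falls below
  1e-6; a single batch short-circuits to the identity with a warning.
* OLS uses QR (via `lm`); the trend fit computes its coefficient
  covariance directly from the QR factors, avoiding `summary.lm`'s
  perfect-fit warnings on noise-free data.
* Bootstrap replicates where a resample yields a degenerate fit are
  dropped and counted (`B_used`); groups with fewer than 3 subjects are
  rejected up front.
* All seeds are 32-bit integers; sub-seeds are derived as
  `(seed + i·1000003) mod 2147483629`.

## Problem sizes used in the test suite

The suite favours many small, targeted simulations over few large ones:
null-calibration runs use 1000 replicates of 60-subject cohorts; bootstrap
coverage uses 60 outer replicates of a 207-subject cohort with B = 200;
effect-recovery runs average 20 replicates of the full three-cohort study;
singleton placement uses 100 replicates. These sizes give Monte-Carlo
standard errors comfortably below the asserted tolerances.

## Known limitations

* The glycan-age shift assumes linear trends; with curvature the shift
  becomes age-dependent in a way a single average does not capture
  (no spline ageing curves are fitted, by design).
* The fixed-effects meta-analysis assumes a common true effect; no
  heterogeneity statistics are computed beyond the per-cohort spread.
* Derived traits computed from batch-corrected peaks no longer sum to
  exactly their pre-correction values; the package treats the corrected
  percentage scale as the analysis scale throughout.
* The paired model supports sibling *pairs* (plus singletons); larger
  family structures would need a richer random-effects design.
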