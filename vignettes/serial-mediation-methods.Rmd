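---
title: "Serial two-mediator analysis of pain and functional dependence: models and methods"
author: "serialmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial two-mediator analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

In arthritis cohorts, usual pain at baseline predicts functional dependence
in basic and instrumental activities of daily living years later.  Two
mechanisms plausibly carry part of that effect: pain raises depressive
symptoms, and pain lowers physical activity; both in turn predict
dependence.  `serialmed` implements the serial two-mediator path model that
quantifies these channels:

* **exposure** `pain`: binary, 1 = usually not free of pain or discomfort;
* **mediator 1** `ds`: depressive symptoms, the CESD-10 sum score,
  log-transformed and standardized;
* **mediator 2** `pa`: physical activity, a PASE-style composite,
  standardized;
* **outcome** `dep_fu`: binary functional dependence at follow-up, from a
  1-5 functional-limitation classification;
* **covariates**: standardized age, sex (0 = female, 1 = male), and
  baseline dependence, adjusted for in every model.

Four regressions give the seven paths:

| model | family | paths |
|---|---|---|
| `dep_fu ~ pain + covs` | logistic | `c` (total effect, log OR) |
| `ds ~ pain + covs` | linear | `a1` (SD units) |
| `pa ~ pain + ds + covs` | linear | `a2`, `a3` (SD units) |
| `dep_fu ~ pain + ds + pa + covs` | logistic | `c'`, `b1`, `b2` (log OR) |

The indirect effect is decomposed by products of coefficients on the
log-odds scale: through depression `a1 b1`, through activity `a2 b2`, and
through the serial chain pain → depression → activity → dependence
`a1 a3 b2`; their sum is the total indirect effect.  The share of the total
effect explained by mediation is summarized by
`100 (c - c') / c`, with each pathway also expressed as a share of `c` and
of the total indirect effect.  Because the outcome models use a nonlinear
link, direct and indirect effects need not add up to the total effect
(non-collapsibility of odds ratios); the percentage-mediated figures are
approximations by construction and the decomposition identity that *is*
exact — the three pathways summing to the total indirect effect — is
asserted in code.

### Ordering of the mediators

The serial model assumes depression acts before activity.  The package also
fits the reverse ordering (`alternate_ordering()`), in which activity is
regressed on pain alone and depression on pain and activity.  Both
orderings share the same outcome model, and because the mediator models are
least squares, the two total indirect effects coincide exactly in sample
(omitted-variable algebra); only the split between single-mediator and
serial pathways is ordering-dependent.  This identity is tested to 1e-10.

## From instruments to model variables

**CESD-10.** Ten items scored 0-3 are summed to 0-30.  A participant with
exactly one missing item has it imputed by the mean of the nine observed
items (the sum is therefore not necessarily an integer and is never
rounded); two or more missing items exclude the participant, and exclusions
are counted and reported.  The sum score is strongly right-skewed with mass
at zero, so models use `log(score + offset)`.  The offset defaults to 1 —
defined at zero and order-preserving — and is configurable
(`log_offset`): standardization absorbs any monotone rescaling of the
transformed score, so this choice moves coefficients only through the shape
of the transform, not its location or scale.

**PASE composite.** The published instrument yields a 0-485 composite from
frequency (1-4) and duration (1-5) responses over five activity
categories.  The exact published weighting lives in the instrument's
scoring manual; `score_pase()` implements a configurable weighted sum whose
shipped default table (`pase_weights()`, version `serialmed-1`) reaches the
same 0-485 range, with weights treated as data, not code.  Cohorts that
already carry a composite column are used as-is.

**Functional dependence.** The 1-5 limitation classification is
dichotomized under the main scheme (classes 1-2 independent, 3-5
dependent) or a strict sensitivity scheme (only class 1 independent).  The
strict scheme can only add outcome-positive participants — a monotonicity
property the tests assert.  A second sensitivity variant replaces the
follow-up classification column with a pre-computed alternative (standing
in for a re-derivation that ignores meal preparation, which this package
deliberately does not attempt to reconstruct).

**Standardization.** Depression, activity, and age are standardized once on
the included analysis sample; the constants are returned
(`ScalingConstants`) and held fixed across bootstrap resamples so that
"one standard deviation" means the same thing in every resample.
Per-resample re-standardization is available behind the `restandardize`
flag for users who prefer the fully resampled pipeline.

## Bootstrap inference

Indirect effects are products of coefficients from different models, so
model-based standard errors are awkward; inference uses the percentile
bootstrap: resample participants with replacement, re-run all four
regressions and the decomposition, and take the 2.5th and 97.5th
percentiles of each quantity over `B` resamples (default `B = 5000`).  A
quantity is flagged significant when its interval excludes zero.  Interval
endpoints use R's default empirical quantile definition (type 7).

Resamples can fail estimation — a single-class outcome when events are
rare, quasi-separation, a singular design.  Failed resamples are redrawn
with the next draws of the seeded stream and counted
(`n_failed_and_redrawn`), keeping the number of retained resamples exactly
`B`; silently dropping failures would bias the intervals at small sample
sizes.  More than `50 B` total draws aborts with an error rather than
returning a quietly unrepresentative distribution.  The whole procedure is
reproducible from a single integer seed.

Path confidence intervals in the report are model-based (t for linear
paths, Wald z for logistic paths) and labeled as such; bootstrap intervals
are labeled percentile.  The two kinds are reported side by side rather
than silently mixed.

### Numerical details

The user-facing fits are `stats::lm()` and `stats::glm()` (binomial family,
IRLS, convergence epsilon 1e-10, at most 100 iterations).  Logistic fits
additionally record the score-vector norm at the solution and raise an
estimation error when any coefficient magnitude exceeds 15 — on a log-odds
scale such values indicate separation-driven divergence rather than signal.

The bootstrap loop re-estimates four models per resample, and calibration
experiments run hundreds of thousands of refits, so resampled refits run
through a compiled kernel (RcppArmadillo): one Gram-matrix pass serves both
least-squares mediator models, and the logistic models use Newton
iterations with a step-halving guard, warm-started at the full-sample
solution.  The kernel is asserted equal to the `lm`/`glm` route to 1e-8 in
the test suite.  Warm-started refits stop when the largest coefficient
change drops below `newton_tol` (default 0.02), which leaves coefficients
within about 1e-4 of their optimum — orders of magnitude below resampling
noise at any realistic sample size; the tolerance is exposed for users who
want resampled coefficients at machine precision.

## The synthetic cohort generator

The cohort data this analysis was designed for are access-restricted, so
the package carries a first-class generator
(`cohort_config()` / `generate_cohort()`) whose defaults encode the study
conditions: 6972 participants, 52.8% with usual pain, depression scores
averaging 5.5 (SD 4.6) on 0-30, activity 185.0 (SD 75.8) on 0-485, 58.7%
female, ages 45-85, under 1% moderate-or-worse baseline limitation, and
default structural coefficients equal to the published path estimates.

The generator draws the structural model on the scales the estimator uses:

1. a depression latent `alpha1 * pain + N(0, 1)`, standardized;
2. an integer 0-30 score via `round(clip(expm1(m + s * z)))`, with `(m, s)`
   solved *exactly* (breakpoint sums of the mixture-normal CDF) so the
   score marginal hits its target mean and SD — a right-skewed,
   zero-inflated integer marginal resembling the instrument's;
3. CESD items allocated unit-by-unit to random non-full items so they sum
   to the score, then at most one item knocked out at the configured
   missingness rate — the participant's analysis score is re-derived
   through the imputation rule itself, so the scoring code is exercised
   end to end;
4. an activity latent `alpha2 * pain + alpha3 * ds_z + N(0, 1)` mapped to
   the 0-485 scale by a clipped affine map, again calibrated by exact
   moment equations of the winsorized normal;
5. a follow-up outcome drawn from the logistic model on the standardized
   *derived* mediators, realized as a 1-5 class so the dichotomization
   code also runs on generated data.

Because the outcome acts on the very variables the analysis constructs,
`cohort_truth()` can state the recoverable path values in closed form:
mediator paths are the latent coefficients divided by the marginal SD of
their latent (e.g. `a1 = alpha1 / sqrt(1 + alpha1^2 p (1 - p))`), and
outcome paths pass through unchanged.  Two approximations remain and are
deliberate: integer rounding of the score map distorts the depression path
by roughly 0.003 (measured against a large Monte-Carlo regression), and
clipping at the scale bounds attenuates the activity path by well under 1%.
Both are far inside the tolerances of the recovery tests.

The log-score map is used instead of a count-family quantile coupling
because a quantile map through a heavily zero-inflated count distribution
has a wide flat region that visibly distorts the recoverable coefficient;
the rounded log-normal map keeps the closed-form truth honest while
preserving the right-skewed integer marginal.

The generator's total effect `c` is left undefined in `cohort_truth()`:
on the log-odds scale the marginal (mediator-free) coefficient implied by a
configuration has no closed form — precisely the non-collapsibility the
decomposition literature warns about — except in the degenerate case of no
mediator effects, where the mediator-free model is the generating model.

**What the generator does not emulate**, and what passing tests therefore
do not show about real data: covariates are independent of pain at baseline
(the joint distribution is not published); age is uniform rather than the
real cohort's banded distribution; PASE and OARS are not simulated at item
level; there is no survey design, attrition, or measurement error beyond
the single-item missingness; and the depression-activity-outcome
dependence is exactly the fitted structural form, so recovery tests
validate the estimator, not the substantive model.

## Validation problem sizes

The test suite checks, at sizes chosen to balance Monte-Carlo resolution
against a single-CPU run: parameter recovery on 20 cohorts of 50,000,
demanding mediator paths within 0.05 and log-odds paths within 0.10 of
generator truth on every cohort, plus across-cohort mean recovery within a
third of those bands.  One caveat is stated rather than hidden: at the
study's ~2% outcome prevalence the direct-effect path has a per-cohort
sampling SD near 0.07, so the 0.10 per-cohort band amounts to a ~1.4-sigma
requirement that no consistent estimator meets on every seed; the pooled
mean check is what separates bias from that sampling noise, and it shows
recovery is unbiased.  Further: percentile-interval coverage of the
depression pathway on 200 replicate cohorts of 20,000 with `B = 999` (the
published procedure used `B = 5000`; 999 preserves percentile resolution
while keeping the experiment tractable), demanding 92-98% empirical
coverage; null-model suites in which every interval should cover zero; and
the exact additive limit: with a continuous outcome and linear outcome
models, `c - c'` equals the total indirect effect to 1e-8, the closed-form
limit of the decomposition that fails on the log-odds scale.

## Known limitations

* The estimands are regression path products, not counterfactual natural
  effects; no exposure-mediator interactions are modeled.
* Missing data beyond the CESD single-item rule is handled by listwise
  deletion with counts, not imputation.
* Logistic confidence intervals are Wald; profile intervals are not
  implemented.
* The percentage-mediated summaries inherit the non-collapsibility caveat
  and should be read as approximate shares.
* Subset analyses re-standardize within the analyzed subset (the modeled
  sample defines the SD unit); whether a published subgroup analysis reused
  full-sample constants is generally unstated, so the report records which
  convention was used.
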