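---
title: "Multilevel meta-analysis of yield variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel meta-analysis of yield variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabmeta)
```

## The problem

Pollination-exclusion experiments compare a yield response between plants
(or flowers, plots, or field sites) that receive an animal-pollination
treatment and auto-pollinated controls. Each published comparison reports
two arm summaries — mean, standard deviation, and number of experimental
units — so beyond the familiar question "does pollination raise mean
yield?", the same tables answer a second one: "does pollination make yield
more *stable* across space?" stabmeta implements the full analysis chain
for that question: variability effect sizes, the sampling dependence
induced by shared control arms, multilevel random-effects estimation, and
the supporting heterogeneity, sensitivity and simulation machinery.

## Effect sizes

For a treatment arm $(\bar x_T, s_T, n_T)$ and control arm
$(\bar x_C, s_C, n_C)$, with $CV = s/\bar x$:

* **lnRR** (mean yield benefit):
  $\ln(\bar x_T/\bar x_C) + \tfrac12\!\left[CV_T^2/n_T - CV_C^2/n_C\right]$,
  sampling variance $CV_T^2/n_T + CV_C^2/n_C$.
* **lnVR** (absolute variability):
  $\ln(s_T/s_C) + \tfrac{1}{2(n_T-1)} - \tfrac{1}{2(n_C-1)}$,
  sampling variance $\tfrac{1}{2(n_T-1)} + \tfrac{1}{2(n_C-1)}$.
* **lnCVR** (variability per unit of mean, the stability measure):
  the lnVR expression minus the lnRR expression; its sampling variance is
  the sum of the two component variances.

The additive correction terms remove the leading-order small-sample bias
of the plug-in log estimators; the package's tests verify by Monte Carlo
that the corrected estimators are mean-unbiased for normal unit yields at
$n = 10$. The cross-term of the full lnCVR variance requires the
within-arm correlation between log mean and log SD, which two-arm summary
tables do not report; it is exposed as `mv_cor` in `lncvr()` and defaults
to zero (off).

Negative lnCVR or lnVR means the treated arm is more stable; lnRR is
reported on the percent scale as $(e^b - 1)\cdot 100$ and the stability
ratios as $(1 - e^b)\cdot 100$ ("percent more stable").

## The arm-based ln(SD) model

lnCVR assumes a 1:1 slope between ln(SD) and ln(mean). To relax that
assumption the suite also fits an arm-based model: one row per
experimental arm with response $\ln s + \tfrac{1}{2(n-1)}$ (bias-corrected
to stay consistent with the contrast-based measures), fixed effects for
the treatment condition and $\ln \bar x$, and sampling variance
$\tfrac{1}{2(n-1)}$. When the ln(mean) coefficient is constrained to 1
(an offset), the condition coefficient coincides with the overall lnCVR
effect — asserted to $10^{-6}$ in the tests on shared-control-free data.
Each distinct control arm enters once, however many treatments it serves.

## Shared controls and the sampling VCV

When several treatment arms are compared with one control arm, the
resulting effect sizes share the control's sampling error. The covariance
between two same-type effect sizes sharing a control is the control arm's
contribution to each sampling variance ($CV_C^2/n_C$ for lnRR,
$\tfrac{1}{2(n_C-1)}$ for lnVR, their sum for lnCVR). `build_vcv()`
assembles the block-diagonal sampling VCV; blocks whose implied
correlations reach 1 are rejected, and negative eigenvalues within
$10^{-10}$ of zero (floating-point rounding) are repaired on the diagonal
with a message. Effect-size types are never mixed in one matrix.

## The multilevel model

`mlma()` fits $y \sim N(X\beta,\; V_s + \sum_l \sigma^2_l Z_l Z_l')$ with
nested random levels (publication / experimental comparison / effect
size; the innermost level carries residual heterogeneity). Variance
components are estimated by REML for reported models and by ML for
likelihood-ratio tests of moderators, profiling $\beta$ by GLS.

Numerical choices:

* optimisation over $\log\sigma^2_l$ with a floor of $10^{-10}$
  (effective zero), bounded L-BFGS-B, analytic gradients (validated
  against numerical differentiation in the tests);
* deterministic multi-start from $\{0.1, 1, 10\} \times$ the mean
  sampling variance; a non-converged start only wins if it beats every
  converged one beyond the objective tolerance, and a stop with a
  vanished projected gradient counts as converged;
* the likelihood is evaluated block-by-block over the independent row
  blocks implied by the random levels and the VCV (publications, in
  practice), which makes a 500-effect fit take well under a second;
* nesting is enforced by compound group labels, so reused inner labels
  cannot leak across publications.

Wald inference uses normal ($z$) quantiles by default, with a $t$ option
(`summary(fit, df = ...)`); the grid-search oracle in the tests pins the
REML solution to 4 decimals on small problems, and cell-means and
reference codings of categorical moderators are verified to give
identical likelihoods. Prediction intervals widen the confidence interval
by the summed random-effect variances:
$\hat\mu \pm z\sqrt{SE^2 + \sum_l \sigma^2_l}$.

For arm-based analyses, where the two arms of a comparison share
experimental material beyond what the diagonal sampling variances
express, `robust()` provides CR2 bias-reduced cluster-robust covariance
with Satterthwaite degrees of freedom, clustered on the experimental
comparison. The CR2 adjustment uses the fitted marginal covariance as the
working model; with singleton clusters it reduces to the
heteroscedasticity-robust form (checked algebraically in the tests).

## Heterogeneity

The typical sampling variance uses the weighted construction
$\tilde v = (k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$, $w_i = 1/v_i$,
computed from the sampling-variance diagonal only (covariances ignored);
an arithmetic-mean alternative is available for sensitivity. Multilevel
$I^2$ partitions $100\,\sigma^2_l/(\sum_m \sigma^2_m + \tilde v)$ across
levels; marginal $R^2$ is the variance of the fitted values as a share of
itself plus the summed variance components, clipped to $[0, 100]$.

## The model suite

`run_suite()` reproduces the full analysis: null models for lnCVR, lnRR
and lnVR plus the arm-based SD0; crop and spatial-scale moderators
(contrast- and arm-based); covariate models for the resource-limitation
hypothesis (lnCVR against lnRR, lnCVR against the z-standardised yield of
treated arms, lnRR against the z-standardised yield of controls); and
pollinator-type and pollination-intensity models. Yield means are
z-standardised within crop × response-measure × spatial-scale groups;
singleton or zero-spread groups give missing covariates and those rows
drop from the affected model only. Covariate models are univariate GLS
fits that treat the covariate as fixed and error-free — no
errors-in-variables correction. Reported estimates come from REML refits
in cell-means coding; LRTs compare ML fits in reference coding. "Plot"
and "cohort" aggregation scales are treated as one level by default
(switchable at load time), and the intensity model runs on the subset of
rows flagged with a high/low intensity contrast, since those experiments
are identified by design rather than by a computable rule.

## Sensitivity analyses

Leave-one-publication-out refits of the null model; repeated refits
keeping one randomly chosen effect size per comparison (seeded,
bit-reproducible); publication year (mean-centred) as a continuous
moderator for time-lag bias; and an Egger-type regression on
$\sqrt{1/\tilde n}$ with $\tilde n = n_T n_C/(n_T + n_C)$ for small-study
asymmetry in the lnRR analysis. The alternative
$\tilde n = 4 n_T n_C/(n_T+n_C)$ is provided since both conventions are
in circulation.

## Synthetic data

Two generators make every stage testable without external data.

The **summary-level generator** (`generate_summary_dataset()`) emulates
the corpus structure: 47 publications, 215 comparisons and 498 effect
sizes by default, with multiple response measures per comparison and
pairs of treatment arms sharing one control. True row effects are
additive on the log scale (overall mean plus independent normal
publication-, comparison- and effect-level deviates with variances
$\{0.05, 0.02, 0.01\}$ by default and true overall lnCVR $-0.4$, lnRR
$0.7$). Unit yields are lognormal — yield is positive and right-skewed,
and multiplicative noise reproduces the strong mean–variance relationship
of real yield data — with arm means and CVs that realise each row's true
effects exactly at the distribution level; sampling noise enters only
through the finite number of units per arm (5–30 by default, spanning
small site-scale experiments to moderate plant-scale ones). One master
seed drives per-publication substreams, so growing the corpus leaves
earlier publications unchanged.

The **resource-ceiling generator** (`generate_ceiling_dataset()`) is
mechanistic: each unit has a lognormal maximum potential yield, animal
pollination multiplies pre-ceiling yield by a gain factor, and realised
yield is the minimum of the two. When the ceiling binds, well-pollinated
units cluster under it, compressing the treated arm's CV — the model-free
route to the negative lnCVR–lnRR association that the covariate models
measure on real data.

What the generators do *not* emulate: correlated sampling errors between
response measures taken on the same units (the analysis model assumes
them uncorrelated, and the generator draws them independently), temporal
(between-year) structure, spatial autocorrelation between fields, and
pollinator foraging behaviour. Passing tests therefore validate the
estimation machinery under the model's own assumptions plus lognormal
skew, not the full messiness of field data.

## Problem sizes used in the checks

The test suite works at deliberately modest scales: Monte-Carlo bias
checks use $10^4$ simulated arm pairs; the grid-search likelihood oracle
uses problems of at most 8 effects at a $10^{-4}$ grid step; the
parameter-recovery study uses 200 corpora at the full default structure
(47 publications, 498 effects), fitted with a single optimiser start
after verifying that multi-start gives identical estimates there; the
ceiling sign test uses 20 seeded runs of 24 comparisons. The acceptance
script runs the complete suite on one default corpus and reports the
headline quantities.

## Known limitations

* The small-sample corrections in lnRR/lnVR/lnCVR are normal-theory.
  Under strongly right-skewed unit yields (as in the lognormal
  generator) the corrected lnCVR estimator retains a positive
  small-sample bias that shrinks roughly like $1/n$ per arm and is
  visible in the recovery study as slight undercoverage of the overall
  effect; with normal unit yields the same checks show no bias. Users
  whose raw data are heavily skewed should read per-arm $n \lesssim 10$
  results conservatively.
* Wald intervals use $z$ quantiles; with few publications a $t$
  calibration (exposed via `summary(fit, df = ...)`) is less
  anti-conservative.
* Random levels must be nested; a crossed cultivar-by-publication effect
  can only be approximated as an extra nested level.
* The lnCVR sampling variance omits the mean–variance correlation
  cross-term unless `mv_cor` is supplied.
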